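#' Experiment configuration
#'
#' A serializable description of a full benchmark experiment: acquisition
#' geometry, noise levels, dataset sizes, masking grid, denoiser and
#' training settings, the methods to run, output directory, and a global
#' seed from which all per-stage seeds are derived.
#'
#' @param geometry A [projection_geometry()].
#' @param noise_levels_db Numeric vector of sinogram SNR levels in dB.
#' @param dataset List with `n_total`, `fractions`, `size`,
#'   `n_ellipses_range`.
#' @param grid A [perturbation_grid()].
#' @param denoiser A [denoiser_config()].
#' @param train List of [train_config()] overrides (`learning_rate`,
#'   `n_iterations`, `batch_size`).
#' @param methods Character vector among `"fbp"`, `"sart"`, `"sart_tv"`,
#'   `"proj2proj"`, `"supervised"`.
#' @param output_dir Directory for benchmark outputs.
#' @param seed Global integer seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(geometry = projection_geometry(128, 64, 128),
                              noise_levels_db = 33,
                              dataset = list(n_total = 10,
                                             fractions = c(0.6, 0.2, 0.2),
                                             size = geometry$image_size,
                                             n_ellipses_range = c(3L, 10L)),
                              grid = perturbation_grid(),
                              denoiser = denoiser_config(3L, 8L),
                              train = list(learning_rate = 1e-3,
                                           n_iterations = 500L,
                                           batch_size = 1L),
                              methods = c("fbp", "sart"),
                              output_dir = tempfile("benchmark_"),
                              seed = 1L) {
  known <- c("fbp", "sart", "sart_tv", "proj2proj", "supervised")
  bad <- setdiff(methods, known)
  if (length(bad) > 0)
    stop_config("unknown method name(s): ", paste(bad, collapse = ", "),
                " (available: ", paste(known, collapse = ", "), ")")
  if (!identical(dataset$size, geometry$image_size))
    stop_config("dataset$size must equal geometry$image_size")
  structure(list(geometry = geometry, noise_levels_db = noise_levels_db,
                 dataset = dataset, grid = grid, denoiser = denoiser,
                 train = train, methods = methods, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_schema <- function() {
  list(geometry = c("image_size", "n_views", "n_detectors",
                    "detector_spacing"),
       dataset = c("n_total", "fractions", "size", "n_ellipses_range"),
       grid = c("cell_rows", "cell_cols"),
       denoiser = c("n_scales", "base_channels", "seed"),
       train = c("learning_rate", "n_iterations", "batch_size"))
}

#' Save / load an experiment configuration as YAML
#'
#' The round trip is lossless (`load_config(save_config(cfg)) == cfg`).
#' Loading validates the schema: a missing required key is an error naming
#' the key; unknown extra keys produce a warning and are ignored.
#'
#' @param cfg An [experiment_config()].
#' @param path YAML file path.
#' @return `load_config` returns an `experiment_config`.
#' @export
save_config <- function(cfg, path) {
  if (!inherits(cfg, "experiment_config"))
    stop_config("cfg must be an experiment_config")
  raw <- list(
    geometry = list(image_size = cfg$geometry$image_size,
                    n_views = cfg$geometry$n_views,
                    n_detectors = cfg$geometry$n_detectors,
                    detector_spacing = cfg$geometry$detector_spacing),
    noise_levels_db = as.numeric(cfg$noise_levels_db),
    dataset = list(n_total = cfg$dataset$n_total,
                   fractions = as.numeric(cfg$dataset$fractions),
                   size = cfg$dataset$size,
                   n_ellipses_range = as.integer(cfg$dataset$n_ellipses_range)),
    grid = list(cell_rows = cfg$grid$cell_rows,
                cell_cols = cfg$grid$cell_cols),
    denoiser = list(n_scales = cfg$denoiser$n_scales,
                    base_channels = cfg$denoiser$base_channels,
                    seed = cfg$denoiser$seed),
    train = cfg$train[c("learning_rate", "n_iterations", "batch_size")],
    methods = cfg$methods,
    output_dir = cfg$output_dir,
    seed = cfg$seed)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  schema <- config_schema()
  top_required <- c(names(schema), "noise_levels_db", "methods",
                    "output_dir", "seed")
  for (key in top_required)
    if (is.null(raw[[key]]))
      stop_config("config is missing required key: '", key, "'")
  extra <- setdiff(names(raw), top_required)
  if (length(extra) > 0)
    warning("ignoring unknown config key(s): ", paste(extra, collapse = ", "))
  for (section in names(schema))
    for (key in schema[[section]])
      if (is.null(raw[[section]][[key]]))
        stop_config("config is missing required key: '", section, ".", key,
                    "'")
  experiment_config(
    geometry = projection_geometry(raw$geometry$image_size,
                                   raw$geometry$n_views,
                                   raw$geometry$n_detectors,
                                   raw$geometry$detector_spacing),
    noise_levels_db = as.numeric(raw$noise_levels_db),
    dataset = list(n_total = raw$dataset$n_total,
                   fractions = as.numeric(raw$dataset$fractions),
                   size = as.integer(raw$dataset$size),
                   n_ellipses_range = as.integer(raw$dataset$n_ellipses_range)),
    grid = perturbation_grid(raw$grid$cell_rows, raw$grid$cell_cols),
    denoiser = denoiser_config(raw$denoiser$n_scales,
                               raw$denoiser$base_channels,
                               seed = raw$denoiser$seed),
    train = raw$train,
    methods = as.character(raw$methods),
    output_dir = raw$output_dir,
    seed = raw$seed)
}

reconstruct_with_method <- function(method, sino, geom, trained) {
  switch(method,
    fbp = fbp_reconstruct(sino, geom),
    sart = sart_reconstruct(sino, geom),
    sart_tv = sart_tv_reconstruct(sino, geom),
    proj2proj = reconstruct(sino, trained$proj2proj, geom),
    supervised = reconstruct(sino, trained$supervised, geom),
    stop_config("unknown method name: ", method))
}

#' Run a benchmark experiment
#'
#' Generates a phantom dataset, simulates noisy sparse-view sinograms at
#' each requested noise level, reconstructs the test split with every
#' requested method (training the learned methods on the training split
#' first), and writes per-method/per-level reports: a CSV of all summaries,
#' a Markdown table (methods x noise levels), and a PNG panel of the first
#' test reconstruction per method. Every artifact records the config hash
#' and seed that produced it. A failing method is logged and skipped;
#' the others continue.
#'
#' @param cfg An [experiment_config()].
#' @return Invisible list of `evaluation_report` objects (one per
#'   method x noise level), named `"method@snr"`.
#' @export
run_benchmark <- function(cfg) {
  if (!inherits(cfg, "experiment_config"))
    stop_config("cfg must be an experiment_config")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), "output_dir")])
  logf <- file.path(cfg$output_dir, "benchmark.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                                "\n", sep = "", file = logf, append = TRUE)
  log_line("benchmark start; config hash ", hash, "; seed ", cfg$seed)

  split <- generate_dataset(cfg$dataset$n_total, cfg$dataset$fractions,
                            cfg$dataset$size, rng_seed = cfg$seed,
                            n_ellipses_range = cfg$dataset$n_ellipses_range)
  geom <- cfg$geometry
  clean_sino <- function(imgs) lapply(imgs, radon_forward, geom = geom)
  sino_clean <- list(train = clean_sino(split$train),
                     validation = clean_sino(split$validation),
                     test = clean_sino(split$test))
  reports <- list()
  needs_training <- intersect(cfg$methods, c("proj2proj", "supervised"))
  for (li in seq_along(cfg$noise_levels_db)) {
    level <- cfg$noise_levels_db[li]
    noisy <- lapply(names(sino_clean), function(part) {
      lapply(seq_along(sino_clean[[part]]), function(i)
        add_noise_snr(sino_clean[[part]][[i]],
                      noise_model(level, seed = child_seed(cfg$seed,
                                                           li * 10000 + i))))
    })
    names(noisy) <- names(sino_clean)
    trained <- list()
    for (m in needs_training) {
      tc <- train_config(geom, cfg$grid,
                         learning_rate = cfg$train$learning_rate,
                         n_iterations = cfg$train$n_iterations,
                         batch_size = cfg$train$batch_size,
                         seed = cfg$seed)
      den <- build_denoiser(cfg$denoiser)
      log_line("training ", m, " at ", level, " dB")
      trained[[m]] <- if (m == "proj2proj")
        train_proj2proj(noisy$train, noisy$validation, den, tc)$denoiser
      else
        train_supervised(Map(function(s, x) list(sinogram = s, target = x),
                             noisy$train, split$train), den, tc)$denoiser
    }
    for (m in cfg$methods) {
      key <- sprintf("%s@%g", m, level)
      res <- tryCatch({
        recs <- lapply(noisy$test, reconstruct_with_method, method = m,
                       geom = geom, trained = trained)
        rep <- evaluate_reconstructions(split$test, recs, method = m,
                                        noise_db = level)
        png_path <- file.path(cfg$output_dir,
                              sprintf("recon_%s_%gdB.png", m, level))
        png::writePNG(pmin(pmax(recs[[1]], 0), 1), png_path)
        log_line(key, ": PSNR ", round(rep$summary$psnr_mean, 2), " dB")
        rep
      }, error = function(e) {
        log_line(key, " FAILED: ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) reports[[key]] <- res
    }
  }
  summaries <- do.call(rbind, lapply(reports, function(r) r$summary))
  summaries$config_hash <- hash
  summaries$seed <- cfg$seed
  write.csv(summaries, file.path(cfg$output_dir, "summary.csv"),
            row.names = FALSE)
  writeLines(markdown_table(reports, hash, cfg$seed),
             file.path(cfg$output_dir, "summary.md"))
  log_line("benchmark done: ", length(reports), " reports")
  invisible(reports)
}

# Methods x noise levels Markdown table ("PSNR mean +/- sd | SSIM ...").
markdown_table <- function(reports, hash = NULL, seed = NULL) {
  if (length(reports) == 0) return("(no successful reports)")
  summaries <- do.call(rbind, lapply(reports, function(r) r$summary))
  methods <- unique(summaries$method)
  levels <- sort(unique(summaries$noise_db))
  header <- paste0("| Method | ",
                   paste(sprintf("%g dB SNR PSNR | %g dB SNR SSIM",
                                 levels, levels), collapse = " | "), " |")
  sep <- paste(rep("|---", 2 * length(levels) + 1), collapse = "")
  rows <- vapply(methods, function(m) {
    cells <- vapply(levels, function(l) {
      s <- summaries[summaries$method == m & summaries$noise_db == l, ]
      if (nrow(s) == 0) return("n/a | n/a")
      sprintf("%.2f +/- %.2f | %.3f +/- %.3f",
              s$psnr_mean, s$psnr_sd, s$ssim_mean, s$ssim_sd)
    }, character(1))
    paste0("| ", m, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  c(header, paste0(sep, "|"), rows, "",
    if (!is.null(hash)) sprintf("config hash: %s; seed: %s", hash,
                                format(seed)))
}
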