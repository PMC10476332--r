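#' Pipeline configuration
#'
#' One document tying together the stage configurations of the full
#' sketch-to-controller pipeline. Defaults are the published training
#' recipe; the `demo` preset shrinks the corpus and epoch counts to
#' something that runs in minutes on one CPU while exercising every
#' stage.
#'
#' @param seed Global seed; every stage derives its randomness from it.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param modes Template modes for the synthetic corpus.
#' @param subjects,reps Corpus size: subjects per mode, repetitions per
#'   subject.
#' @param gan A [gan_config()].
#' @param presets List of [mode_preset()]s to build datasets for.
#' @param controller_epochs,controller_batch Controller training
#'   parameters.
#' @param demo If TRUE, shrink to a smoke-test scale (overrides the
#'   corpus and epoch arguments).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "gaitforge-out",
                            modes = c("lgw", "stairs_up"),
                            subjects = 5L, reps = 10L,
                            gan = gan_config(seed = seed),
                            presets = list(mode_preset("lgw")),
                            controller_epochs = 15L,
                            controller_batch = 256L,
                            demo = FALSE) {
  if (demo) {
    subjects <- 3L; reps <- 4L
    gan <- gan_config(epochs = 20L, seed = seed)
    presets <- list(mode_preset("lgw", variations = 6L, datasets = 2L))
    controller_epochs <- 3L
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir, modes = modes,
                 subjects = subjects, reps = reps, gan = gan,
                 presets = presets,
                 controller_epochs = as.integer(controller_epochs),
                 controller_batch = as.integer(controller_batch)),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) (seed * 1009L + k * 7919L) %% 2147483647L

#' Run the full pipeline
#'
#' Executes corpus generation, GAN training, sketch-conditioned pattern
#' generation, dataset building, controller training and evaluation,
#' writing every artifact under `cfg$out_dir` together with a JSON
#' manifest recording the seed and the files produced. Identical
#' configurations produce identical manifests.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest (list), invisibly; written to
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(f) files <<- c(files, f)

  # 1. synthetic training corpus
  corpus <- make_corpus(cfg$modes, cfg$subjects, cfg$reps,
                        seed = stage_seed(cfg$seed, 1L))

  # 2. GAN
  gan_cfg <- cfg$gan; gan_cfg$seed <- stage_seed(cfg$seed, 2L)
  gan <- train_gan(corpus, gan_cfg)

  # 3. reference sketches + generated patterns per mode
  norm <- normalization_spec("benchmark")
  ref_weight <- 70
  sketches <- lapply(cfg$modes, function(m) {
    tp <- template_pattern(gait_template(m), weight = ref_weight)
    discretize(normalize_pattern(tp, norm, weight = ref_weight))
  })
  names(sketches) <- cfg$modes
  reports <- list()
  for (m in cfg$modes) {
    gen <- smooth_output(generate(sketches[[m]], gan))
    f <- file.path(cfg$out_dir, paste0("pattern_", m, ".csv"))
    write_pattern_csv(gen, f); note(f)
    ref <- drop_endpoint(normalize_pattern(
      template_pattern(gait_template(m), weight = ref_weight),
      norm, weight = ref_weight))
    rep <- evaluate_pair(ref, gen)
    rf <- file.path(cfg$out_dir, paste0("report_", m, ".json"))
    write_metric_report(rep, rf); note(rf)
    reports[[m]] <- rep$overall
  }

  # 4. controller datasets from the first preset's mode
  preset <- cfg$presets[[1]]
  sk <- sketches[[preset$mode]] %||% sketches[[1]]
  datasets <- build_dataset(preset, gan, sk,
                            seed = stage_seed(cfg$seed, 3L))
  for (i in seq_along(datasets)) {
    f <- file.path(cfg$out_dir, sprintf("dataset_%02d.csv", i))
    write_timeseries_csv(datasets[[i]], f); note(f)
  }

  # 5. controllers
  windows <- merge_windows(lapply(datasets, make_windows))
  ctrl <- train_controllers(windows, seed = stage_seed(cfg$seed, 4L),
                            epochs = cfg$controller_epochs,
                            batch = cfg$controller_batch)

  # 6. offline command replay on the first dataset
  cmds <- simulate_commands(datasets[[1]], ctrl)
  f <- file.path(cfg$out_dir, "commands.csv")
  utils::write.csv(cmds, f, row.names = FALSE); note(f)

  manifest <- list(
    seed = cfg$seed,
    corpus_pairs = length(corpus),
    gan = list(epochs = gan$train_state$epochs,
               final_g_loss = unname(tail_val(gan$train_state$traces$g_loss)),
               final_d_loss = unname(tail_val(gan$train_state$traces$d_loss))),
    evaluation = reports,
    datasets = length(datasets),
    controller = list(
      epochs = ctrl$train_state$epochs,
      final_eq_mse = tail_val(ctrl$train_state$eq_trace),
      final_kb_mse = tail_val(ctrl$train_state$kb_trace)),
    files = files,
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

tail_val <- function(x) x[length(x)]
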