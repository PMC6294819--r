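# End-to-end orchestration: simulate -> extract -> screen -> predict from a
# single declarative configuration, with provenance stamped into every
# output file (package version, configuration hash, master seed).

#' Pipeline run configuration
#'
#' @param mode one of `"simulate"`, `"extract"`, `"screen"`, `"predict"`,
#'   `"full"`.
#' @param out_dir output directory (created if absent).
#' @param manifest recording manifest path or data.frame (`extract` mode).
#' @param cohort cohort table path or data.frame (`screen`/`predict`).
#' @param features feature table path or data.frame (`screen`/`predict`).
#' @param n_subjects synthetic cohort size (`simulate`/`full`).
#' @param n_audio_subjects how many simulated subjects also get WAV + truth
#'   sidecar files (audio synthesis is the expensive part; the cohort-level
#'   statistics never need it).
#' @param audio_tasks task codes simulated per audio subject.
#' @param responses response columns for the prediction stage.
#' @param dimensions HD dimensions for the prediction stage.
#' @param planted optional planted partial-correlation data.frame (see
#'   [cohort_spec]).
#' @param seed master seed; every stage derives its own stream from it.
#' @param config an [hd_config] of analysis parameters.
#' @param config_file optional YAML file whose entries override the
#'   arguments above (file wins; flags-last semantics).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("full", "simulate", "extract", "screen",
                                     "predict"),
                            out_dir = tempfile("hdspeech_run_"),
                            manifest = NULL, cohort = NULL, features = NULL,
                            n_subjects = 75, n_audio_subjects = 2,
                            audio_tasks = c("TSK4", "TSK5", "TSK10"),
                            responses = "dtotal",
                            dimensions = "combination",
                            planted = NULL,
                            seed = 1, config = hd_config(),
                            config_file = NULL) {
  mode <- match.arg(mode)
  pc <- list(mode = mode, out_dir = out_dir, manifest = manifest,
             cohort = cohort, features = features, n_subjects = n_subjects,
             n_audio_subjects = n_audio_subjects, audio_tasks = audio_tasks,
             responses = responses, dimensions = dimensions,
             planted = planted, seed = seed, config = config)
  if (!is.null(config_file)) {
    over <- yaml::read_yaml(config_file)
    hd_over <- intersect(names(over), names(hd_config()))
    if (length(hd_over)) pc$config[hd_over] <- over[hd_over]
    over <- over[setdiff(names(over), hd_over)]
    bad <- setdiff(names(over), names(pc))
    if (length(bad)) stop("unknown config entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    pc[names(over)] <- over
  }
  structure(pc, class = "pipeline_config")
}

provenance_lines <- function(pc) {
  c(sprintf("hdspeech %s", as.character(utils::packageVersion("hdspeech"))),
    sprintf("config %s", config_hash(unclass(pc$config))),
    sprintf("seed %s", format(pc$seed)))
}

#' Run the analysis pipeline
#'
#' `simulate` writes a synthetic cohort (`cohort.tsv`, `features.tsv`,
#' `truth.json`) and, for the first `n_audio_subjects` subjects, per-task
#' WAV files with JSON truth sidecars plus a recording manifest.
#' `extract` runs batch feature extraction over a manifest. `screen` runs
#' the three-family partial-correlation screen. `predict` runs the
#' cross-validated boosted-tree prediction per response and dimension.
#' `full` chains simulate, screen and predict on the simulated data, so the
#' outputs mirror the shape of the clinical analysis (a screen report and a
#' per-dimension prediction table) with known ground truth. Two runs with
#' the same configuration and seed produce bitwise-identical text outputs.
#'
#' @param pc a [pipeline_config].
#' @return Named list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(pc) {
  stopifnot(inherits(pc, "pipeline_config"))
  dir.create(pc$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- provenance_lines(pc)
  arts <- list()

  load_tab <- function(x) {
    if (is.character(x)) read.delim(x, comment.char = "#",
                                    stringsAsFactors = FALSE) else x
  }

  if (pc$mode %in% c("simulate", "full")) {
    co <- synth_cohort(cohort_spec(n_subjects = pc$n_subjects,
                                   planted = pc$planted,
                                   seed = derive_seed(pc$seed, 1)))
    write_cohort(co, pc$out_dir, provenance = prov)
    arts$cohort <- file.path(pc$out_dir, "cohort.tsv")
    arts$features <- file.path(pc$out_dir, "features.tsv")
    arts$truth <- file.path(pc$out_dir, "truth.json")

    if (pc$n_audio_subjects > 0) {
      wav_dir <- file.path(pc$out_dir, "audio")
      dir.create(wav_dir, showWarnings = FALSE)
      man <- NULL
      for (si in seq_len(min(pc$n_audio_subjects, pc$n_subjects))) {
        sid <- sprintf("S%03d", si)
        for (tk in pc$audio_tasks) {
          sd0 <- derive_seed(pc$seed, 1000 + si * 20 + match(tk, hd_tasks()$code))
          out <- switch(tk,
            TSK2 = , TSK3 = , TSK4 = synth_phonation(
              phonation_spec(duration = 4, seed = sd0)),
            TSK5 = synth_ddk(ddk_spec(seed = sd0)),
            synth_read_speech(read_speech_spec(seed = sd0)))
          wav <- file.path(wav_dir, sprintf("%s_%s.wav", sid, tk))
          write_wav(out$signal, wav)
          jsonlite::write_json(out$truth,
                               sub("\\.wav$", "_truth.json", wav),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE)
          man <- rbind(man, data.frame(subject_id = sid, session = 1,
                                       task = tk,
                                       path = file.path("audio", basename(wav)),
                                       stringsAsFactors = FALSE))
        }
      }
      man_path <- file.path(pc$out_dir, "manifest.tsv")
      write.table(man, man_path, sep = "\t", row.names = FALSE, quote = FALSE)
      arts$manifest <- man_path
    }
    features <- co$features
    cohort <- co$cohort
  }

  if (pc$mode == "extract") {
    if (is.null(pc$manifest)) stop("extract mode needs a manifest", call. = FALSE)
    man <- load_tab(pc$manifest)
    if (is.character(pc$manifest)) {
      # manifest paths are stored relative to the manifest's own directory
      rel <- !grepl("^(/|[A-Za-z]:)", man$path)
      man$path[rel] <- file.path(dirname(pc$manifest), man$path[rel])
    }
    ft <- extract_features(man, pc$config)
    p <- file.path(pc$out_dir, "features_long.tsv")
    write_feature_table(ft, p, provenance = prov)
    arts$features <- p
    return(invisible(arts))
  }

  if (pc$mode %in% c("screen", "predict")) {
    features <- load_tab(pc$features)
    cohort <- load_tab(pc$cohort)
    if (is.null(features) || is.null(cohort))
      stop(pc$mode, " mode needs 'features' and 'cohort'", call. = FALSE)
  }

  if (pc$mode %in% c("screen", "full")) {
    fcols <- intersect(names(features), dimension_features("combination"))
    scr <- fog_screen(features[c("subject_id", "session", fcols)], cohort,
                      config = pc$config)
    p <- file.path(pc$out_dir, "screen.tsv")
    write_screen(scr, p, provenance = prov)
    arts$screen <- p
  }

  if (pc$mode %in% c("predict", "full")) {
    tab <- fog_predict_table(features, pc$responses, pc$dimensions,
                             config = pc$config,
                             seed = derive_seed(pc$seed, 2))
    p <- file.path(pc$out_dir, "prediction.tsv")
    con <- file(p, "w")
    writeLines(paste0("# ", prov), con)
    write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    jsonlite::write_json(tab, file.path(pc$out_dir, "prediction.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    arts$prediction <- p
  }
  invisible(arts)
}
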