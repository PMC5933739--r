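#' Run the full analysis pipeline
#'
#' Wires the stages end to end: simulate a labelled cohort, compute
#' features and rule labels, rasterize the chosen stage to images, train
#' and evaluate the recognition network by repeated holdout, and produce
#' the stage frequency tables, score transition and presence-of-strategy
#' comparisons. Every stage writes plain files (CSV/PNG/JSON/YAML) into
#' `out_dir` together with the fully resolved configuration and seed, so a
#' second run with the same configuration reproduces all non-stochastic
#' artifacts bit for bit.
#'
#' @param out_dir output directory.
#' @param n_control,n_lesion cohort sizes.
#' @param image_size,classes,epochs,batch_size,dropout,learning_rate
#'   recognition settings (see [cnn_config()]).
#' @param repetitions holdout repetitions.
#' @param stage stage whose images feed the network.
#' @param seed master seed for the whole run.
#' @param write_images whether to write the per-trial PNGs.
#' @param dry_run print the stage plan and write nothing.
#' @param verbose print stage progress.
#' @return a list report: cohort manifest, feature table, evaluation
#'   summary, frequency tables, score transition and outcome comparisons.
#' @export
run_end_to_end <- function(out_dir,
                           n_control = 22, n_lesion = 28,
                           image_size = 48, classes = 2, epochs = 50,
                           batch_size = 32, dropout = 0.5,
                           learning_rate = 1e-3, repetitions = 10,
                           stage = "early", seed = 1,
                           write_images = TRUE, dry_run = FALSE,
                           verbose = FALSE) {
  plan <- c("simulate", "featurize", "rasterize", "evaluate", "analyze")
  if (dry_run) {
    cat("stage plan:", paste(plan, collapse = " -> "), "\n")
    return(invisible(plan))
  }
  cfg <- list(n_control = n_control, n_lesion = n_lesion,
              image_size = image_size, classes = classes, epochs = epochs,
              batch_size = batch_size, dropout = dropout,
              learning_rate = learning_rate, repetitions = repetitions,
              stage = stage, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  say <- function(...) if (verbose) message(...)

  say("simulate: ", n_control + n_lesion, " mice")
  cohort <- simulate_cohort(
    cohort_spec(n_control = n_control, n_lesion = n_lesion, seed = seed))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  say("featurize")
  feats <- cohort_features(cohort)
  feats$rule_label <- classify_by_rules(feats)
  readr::write_csv(feats, file.path(out_dir, "features.csv"),
                   progress = FALSE)

  say("rasterize: ", stage, " stage at ", image_size, "x", image_size)
  dataset <- build_dataset(cohort, image_size, classes = classes,
                           seed = seed, stage = stage)
  if (write_images) {
    write_dataset_images(dataset, file.path(out_dir, "images"))
  }

  say("evaluate: ", repetitions, " holdout repetitions")
  config <- cnn_config(image_size = image_size, n_classes = classes,
                       epochs = epochs, batch_size = batch_size,
                       dropout = dropout, learning_rate = learning_rate,
                       seed = seed)
  eval_res <- repeated_holdout(dataset, config, repetitions = repetitions,
                               seed = seed)
  jsonlite::write_json(
    list(metrics = as.list(glance(eval_res)), config = cfg,
         per_repetition = tidy(eval_res)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(
    as_tibble(as.data.frame(eval_res$confusion_counts)),
    file.path(out_dir, "confusion.csv"), progress = FALSE)

  say("analyze")
  tab_early <- stage_frequency_table(cohort, "early")
  tab_late <- stage_frequency_table(cohort, "late")
  readr::write_csv(tab_early, file.path(out_dir, "table_early.csv"),
                   progress = FALSE)
  readr::write_csv(tab_late, file.path(out_dir, "table_late.csv"),
                   progress = FALSE)
  transition <- score_transition(cohort)
  readr::write_csv(transition, file.path(out_dir, "score_transition.csv"),
                   progress = FALSE)
  outcomes <- dplyr::bind_rows(
    presence_outcome(cohort, "Thigmotaxis", "early"),
    presence_outcome(cohort, "Direct swim", "early"))
  readr::write_csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   progress = FALSE)

  invisible(list(manifest = cohort_manifest(cohort), features = feats,
                 evaluation = eval_res, table_early = tab_early,
                 table_late = tab_late, transition = transition,
                 outcomes = outcomes, config = cfg))
}
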