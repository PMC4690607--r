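#' Run the full simulate-to-evaluate pipeline on synthetic recordings
#'
#' For each condition, simulates `config$n_recordings` line-scan
#' recordings, detects and tracks every membrane, corrects photobleaching,
#' smooths, segments beats and extracts metrics; then performs the
#' stratified split, trains the bagged forest, applies importance-guided
#' model reduction, predicts the validation set and builds the evaluation
#' report.
#'
#' @param config A [synth_config()] object.
#' @param seed Integer seed driving simulation, split and training.
#' @param smooth_window Moving-average window in lines (default 50).
#' @param train_fraction Stratified training fraction (default 0.33).
#' @param n_trees Trees per forest (default 50).
#' @param reduce Apply [reduce_model()] (default TRUE).
#' @return List with `features`, `split`, `model`, `reduction`,
#'   `predictions`, `report`, and per-recording `qc` (beats detected and
#'   rejected).
#' @export
run_pipeline <- function(config, seed = 1L, smooth_window = 50,
                         train_fraction = 0.33, n_trees = 50,
                         reduce = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  metrics_list <- list(); labels <- c(); rec_ids <- c(); mem_ids <- c()
  qc <- list()
  k <- 0L
  for (cond in config$conditions) {
    for (ri in seq_len(config$n_recordings)) {
      k <- k + 1L
      sim <- simulate_recording(config, cond$label, seed = seed + 1000L * k)
      rec <- sim$recording
      centers <- detect_membranes(rec)
      for (mi in seq_along(centers)) {
        trace <- track_membrane(rec, centers[mi],
                                membrane_id = paste0("m", mi))
        norm <- correct_photobleach(trace)$trace
        sm <- smooth_trace(norm, window = smooth_window)
        beats <- detect_beats(sm)
        cm <- compute_metrics(beats, sm)
        rid <- sprintf("%s_r%d", cond$label, ri)
        metrics_list[[length(metrics_list) + 1L]] <- cm$metrics
        labels <- c(labels, cond$label)
        rec_ids <- c(rec_ids, rid)
        mem_ids <- c(mem_ids, paste0("m", mi))
        qc[[length(qc) + 1L]] <- data.frame(
          recording_id = rid, membrane_id = paste0("m", mi),
          n_beats = beats$n_beats, n_rejected = nrow(cm$rejected),
          beat_rate = beats$beat_rate, true_rate = sim$truth$beat_rate,
          stringsAsFactors = FALSE)
      }
    }
  }
  features <- build_feature_table(metrics_list, labels, rec_ids, mem_ids)
  split <- stratified_split(features, fraction = train_fraction,
                            seed = seed)
  model <- train_forest(split$train, n_trees = n_trees, seed = seed)
  reduction <- NULL
  if (reduce) {
    reduction <- reduce_model(split$train, split$validation,
                              n_trees = n_trees, seed = seed)
    model <- reduction$model
  }
  predictions <- predict(model, split$validation)
  report <- evaluate_predictions(predictions)
  list(features = features, split = split, model = model,
       reduction = reduction, predictions = predictions,
       report = report, qc = do.call(rbind, qc))
}
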