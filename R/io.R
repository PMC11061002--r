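# CSV schemas shared by the simulator, the analysis pipeline and the
# optional loader for externally collected data. All tables round-trip
# through read/write to identical in-memory data frames.

#' Write and read cohort tables
#'
#' `write_cohort_csv()` writes `records.csv` (one row per participant) and
#' `trajectories.csv` (one row per harvest event) into a directory;
#' `read_cohort_csv()` reads them back. The same schema accepts externally
#' collected data: a records table needs `participant_id`, trait columns,
#' `rounds_lasted` and `total_rewards`.
#'
#' @param cohort A [simulate_cohort()] result or compatible list.
#' @param dir Directory to write into (created if missing).
#' @return `write_cohort_csv()` the paths written, invisibly;
#'   `read_cohort_csv()` a list with `records` and `trajectories`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             trajectories = file.path(dir, "trajectories.csv"))
  utils::write.csv(cohort$records, paths["records"], row.names = FALSE)
  if (!is.null(cohort$trajectories)) {
    utils::write.csv(cohort$trajectories, paths["trajectories"],
                     row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  rec_path <- file.path(dir, "records.csv")
  if (!file.exists(rec_path)) {
    stop_validation(sprintf("no records.csv under '%s'", dir))
  }
  records <- utils::read.csv(rec_path)
  traj_path <- file.path(dir, "trajectories.csv")
  trajectories <- if (file.exists(traj_path)) utils::read.csv(traj_path)
  list(records = records, trajectories = trajectories)
}

#' Write and read a solved policy table
#'
#' CSV with columns `state`, `harvest`, `value`.
#'
#' @param policy A [solve_mdp()] policy table.
#' @param file Path to write/read.
#' @return The path / a data frame.
#' @export
write_policy_csv <- function(policy, file) {
  utils::write.csv(as.data.frame(policy)[, c("state", "harvest", "value")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_policy_csv
#' @export
read_policy_csv <- function(file) {
  utils::read.csv(file)
}

#' Write trajectory events for a list of played games
#'
#' @param trajectories List of [play_game()] results.
#' @param file Path for the event-level CSV.
#' @param ids Optional participant identifiers (default `seq_along`).
#' @return The combined event data frame, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, file,
                                   ids = seq_along(trajectories)) {
  rows <- Map(function(tr, id) {
    cbind(participant_id = id, tr$events)
  }, trajectories, ids)
  events <- do.call(rbind, rows)
  utils::write.csv(events, file, row.names = FALSE)
  invisible(events)
}
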