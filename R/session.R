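#' Construct a session of PGG blocks for one subject
#'
#' A session bundles one subject's trial records across blocks with the
#' subject's control-block contribution rate (the proportion of
#' contribution decisions in the non-feedback PGG, used to seed both the
#' initial belief about others and the inequity-aversion baseline).
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param trials Data frame with one row per trial and columns `block`,
#'   `k`, `round`, `decision` (1 = contribute, 0 = free-ride),
#'   `n_free_others` (free-riders among the `N - 1` others), `success`,
#'   `group_reward`. Rows must be ordered by block then round.
#' @param control_rate Contribution proportion in the control (non-feedback)
#'   blocks, in `[0, 1]`.
#' @param cfg A [pgg_config()] giving the task constants.
#' @return An object of class `pgg_session`.
#' @export
pgg_session <- function(subject_id, trials, control_rate, cfg = pgg_config()) {
  trials <- as.data.frame(trials)
  needed <- c("block", "k", "round", "decision", "n_free_others",
              "success", "group_reward")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0L) stop("trials must contain at least one round")
  if (!is.numeric(control_rate) || control_rate < 0 || control_rate > 1) {
    stop("control_rate must lie in [0, 1]")
  }
  if (any(!trials$decision %in% c(0, 1))) stop("decision must be 0/1")
  if (any(trials$n_free_others < 0 | trials$n_free_others > cfg$N - 1)) {
    stop("n_free_others must lie in [0, N - 1]")
  }
  # success must be consistent with the threshold rule
  n_contrib <- trials$decision + (cfg$N - 1 - trials$n_free_others)
  if (any(trials$success != as.integer(n_contrib >= trials$k))) {
    stop("success column inconsistent with the threshold rule")
  }
  if (any(trials$group_reward != cfg$R * trials$success)) {
    stop("group_reward must be R * success")
  }
  for (b in unique(trials$block)) {
    r <- trials$round[trials$block == b]
    if (!identical(as.integer(r), seq_along(r))) {
      stop("rounds within block ", b, " must be 1..T in order")
    }
    if (length(unique(trials$k[trials$block == b])) != 1L) {
      stop("k must be constant within block ", b)
    }
  }
  trials$payoff <- pgg_payoff(trials$decision, trials$success, cfg)
  structure(list(subject_id = as.character(subject_id),
                 trials = trials,
                 control_rate = control_rate,
                 cfg = cfg),
            class = "pgg_session")
}

#' @export
print.pgg_session <- function(x, ...) {
  cat(sprintf(
    "PGG session: subject %s, %d blocks x %d rounds, control rate %.2f\n",
    x$subject_id, length(unique(x$trials$block)),
    max(x$trials$round), x$control_rate))
  invisible(x)
}

#' Write sessions to delimited text files
#'
#' Writes `trials.tsv` (one row per trial, all subjects) and
#' `subjects.tsv` (subject-level sidecar with `control_rate`) into `dir`.
#' The pair round-trips losslessly through [read_sessions()].
#'
#' @param sessions A list of [pgg_session()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sessions <- function(sessions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trials <- do.call(rbind, lapply(sessions, function(s) {
    cbind(subject = s$subject_id,
          s$trials[, c("block", "k", "round", "decision", "n_free_others",
                       "success", "group_reward")])
  }))
  subjects <- data.frame(
    subject = vapply(sessions, function(s) s$subject_id, character(1)),
    control_rate = vapply(sessions, function(s) s$control_rate, numeric(1))
  )
  paths <- c(trials = file.path(dir, "trials.tsv"),
             subjects = file.path(dir, "subjects.tsv"))
  write.table(trials, paths[["trials"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(subjects, paths[["subjects"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read sessions written by [write_sessions()]
#'
#' @param dir Directory containing `trials.tsv` and `subjects.tsv`.
#' @param cfg A [pgg_config()] giving the task constants.
#' @return A list of [pgg_session()] objects, ordered as in `subjects.tsv`.
#' @export
read_sessions <- function(dir, cfg = pgg_config()) {
  tpath <- file.path(dir, "trials.tsv")
  spath <- file.path(dir, "subjects.tsv")
  if (!file.exists(tpath) || !file.exists(spath)) {
    stop("expected trials.tsv and subjects.tsv under ", dir)
  }
  trials <- read.delim(tpath, colClasses = c(subject = "character"))
  subjects <- read.delim(spath, colClasses = c(subject = "character"))
  lapply(seq_len(nrow(subjects)), function(j) {
    id <- subjects$subject[j]
    pgg_session(id, trials[trials$subject == id,
                           setdiff(names(trials), "subject")],
                control_rate = subjects$control_rate[j], cfg = cfg)
  })
}
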