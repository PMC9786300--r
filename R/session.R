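.session_cols <- c("timestamp", "action", "mode", "loss_type", "alpha2",
                   "phi0_deg", "phi1_deg", "delta_mix_ppm",
                   "delta_form1_ppm", "pivot", "loss_value", "n_evals",
                   "mix_sha", "form1_sha", "form2_sha")

#' Create an empty session log
#'
#' The session log is an append-only record of every fit or manual action
#' with the full parameter state, allowing an analysis to be paused,
#' restarted and audited. Angles are logged in degrees (the spectroscopist's
#' unit at external boundaries); the `*_sha` columns hold content
#' fingerprints of the input files.
#'
#' @return A zero-row data frame of class `session_log` with the fixed
#'   column set.
#' @export
session_log <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(.session_cols)), .session_cols),
    stringsAsFactors = FALSE)
  for (nm in c("alpha2", "phi0_deg", "phi1_deg", "delta_mix_ppm",
               "delta_form1_ppm", "loss_value"))
    df[[nm]] <- numeric(0)
  for (nm in c("pivot", "n_evals")) df[[nm]] <- integer(0)
  class(df) <- c("session_log", "data.frame")
  df
}

#' Append an action to a session log
#'
#' Appends exactly one row; existing rows are never modified. Replaying the
#' parameters of the final row through mode `"fixed"` reproduces the logged
#' loss (see [replay_session()]).
#'
#' @param log A [session_log()].
#' @param action Free-form action tag (e.g. `"fit"`, `"fit_raw"`,
#'   `"manual"`).
#' @param mode,loss_type Estimation mode and loss of the logged state.
#' @param params A [deconv_params()].
#' @param loss_value The loss at `params`.
#' @param n_evals Optimiser evaluation count (`NA` for manual entries).
#' @param fingerprints Named character vector with entries `mix`, `form1`,
#'   `form2`: content fingerprints of the input files (see
#'   [file_fingerprint()]).
#' @param timestamp Override the timestamp (default: current UTC time).
#' @return The extended `session_log`.
#' @export
log_action <- function(log, action, mode, loss_type, params, loss_value,
                       n_evals = NA_integer_,
                       fingerprints = c(mix = NA_character_,
                                        form1 = NA_character_,
                                        form2 = NA_character_),
                       timestamp = NULL) {
  stopifnot(inherits(log, "session_log"), inherits(params, "deconv_params"))
  if (is.null(timestamp))
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  row <- data.frame(
    timestamp = timestamp, action = action, mode = mode,
    loss_type = loss_type, alpha2 = params$alpha2,
    phi0_deg = params$phi0 * 180 / pi, phi1_deg = params$phi1 * 180 / pi,
    delta_mix_ppm = params$delta_mix,
    delta_form1_ppm = params$delta_form1,
    pivot = as.integer(params$pivot_index), loss_value = loss_value,
    n_evals = as.integer(n_evals),
    mix_sha = as.character(fingerprints[["mix"]]),
    form1_sha = as.character(fingerprints[["form1"]]),
    form2_sha = as.character(fingerprints[["form2"]]),
    stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(log), row)
  class(out) <- c("session_log", "data.frame")
  out
}

#' Content fingerprint of a file
#'
#' MD5 content fingerprint used to tie session-log rows to their exact input
#' files; a mismatch on replay means the supplied file is not the one the
#' log was recorded against.
#'
#' @param path File path.
#' @return Character fingerprint.
#' @export
file_fingerprint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  unname(tools::md5sum(path))
}

#' Write / read a session log CSV
#'
#' Fixed header
#' `timestamp,action,mode,loss_type,alpha2,phi0_deg,phi1_deg,delta_mix_ppm,delta_form1_ppm,pivot,loss_value,n_evals,mix_sha,form1_sha,form2_sha`.
#'
#' @param log A [session_log()].
#' @param path CSV path.
#' @return `write_session_log`: invisibly, `path`;
#'   `read_session_log`: a `session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  write_csv_raw(as.data.frame(log), path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop("session log not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), .session_cols))
    stop("not a session log (unexpected columns): ", path)
  for (nm in c("alpha2", "phi0_deg", "phi1_deg", "delta_mix_ppm",
               "delta_form1_ppm", "loss_value"))
    df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("pivot", "n_evals")) df[[nm]] <- as.integer(df[[nm]])
  class(df) <- c("session_log", "data.frame")
  df
}

#' Replay the final logged state
#'
#' Re-applies the parameters of the last session-log row to the supplied
#' spectra in mode `"fixed"` and compares the resulting loss with the logged
#' one (relative tolerance `1e-9`). Whether the original fit normalised the
#' spectrum set is restored from the action tag (`"fit_raw"` = no
#' normalisation).
#'
#' @param log A [session_log()] or path to a session-log CSV.
#' @param mix,form1,form2 The original input spectra.
#' @return List with `ok` (logical), `loss_logged`, `loss_replayed`, and the
#'   `deconv_result` of the replay.
#' @export
replay_session <- function(log, mix, form1, form2) {
  if (is.character(log)) log <- read_session_log(log)
  stopifnot(inherits(log, "session_log"))
  if (!nrow(log)) stop("session log is empty")
  row <- log[nrow(log), ]
  params <- deconv_params(alpha2 = row$alpha2,
                          phi0 = row$phi0_deg * pi / 180,
                          phi1 = row$phi1_deg * pi / 180,
                          delta_mix = row$delta_mix_ppm,
                          delta_form1 = row$delta_form1_ppm,
                          pivot_index = row$pivot)
  cfg <- fit_config(mode = "fixed", loss_type = row$loss_type,
                    start = params,
                    normalize = !grepl("_raw$", row$action))
  res <- deconv_fit(mix, form1, form2, cfg)
  ok <- abs(res$loss_value - row$loss_value) <=
    1e-9 * max(abs(row$loss_value), .Machine$double.xmin)
  list(ok = ok, loss_logged = row$loss_value,
       loss_replayed = res$loss_value, result = res)
}
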