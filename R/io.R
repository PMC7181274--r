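#' Write a recording to CSV
#'
#' Wide table: one row per sample, one column per channel plus a `label`
#' column; missing entries are written as empty cells. The sampling rate is
#' recorded in a `# sampling_rate:` comment line before the header.
#'
#' @param rec A `sensor_recording`.
#' @param path Output CSV path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "sensor_recording"))
  V <- rec$values
  V[rec$missing_mask] <- NA
  df <- as.data.frame(V)
  names(df) <- rec$channel_names
  df$label <- rec$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %.10g", rec$sampling_rate), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording_csv()]: empty cells become missing entries.
#'
#' @param path CSV path.
#' @param sampling_rate Override for files without the rate comment line.
#' @return A `sensor_recording`.
#' @export
read_recording_csv <- function(path, sampling_rate = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^# sampling_rate:", first)) {
    if (is.null(sampling_rate))
      sampling_rate <- as.numeric(sub("^# sampling_rate:", "", first))
    df <- utils::read.csv(path, skip = 1)
  } else {
    df <- utils::read.csv(path)
  }
  if (is.null(sampling_rate))
    stop_invalid("sampling_rate not in file and not supplied")
  if (!"label" %in% names(df)) stop_invalid("CSV must contain a 'label' column")
  labels <- as.integer(df$label)
  V <- as.matrix(df[setdiff(names(df), "label")])
  mask <- is.na(V)
  new_sensor_recording(V, mask, labels, sampling_rate,
                       colnames(V))
}

#' Write a window set to CSV
#'
#' Long layout: columns `window`, `t` (0-based sample within window), one
#' column per channel, and `label` (repeated per row of a window).
#'
#' @param ws A `window_set`.
#' @param path Output CSV path.
#' @export
write_windowset_csv <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  d <- dim(ws$data)
  N <- d[1]; T <- d[2]; C <- d[3]
  flat <- matrix(aperm(ws$data, c(2, 1, 3)), N * T, C)
  df <- data.frame(window = rep(seq_len(N) - 1L, each = T),
                   t = rep(seq_len(T) - 1L, N))
  for (c in seq_len(C)) df[[ws$channel_names[c]]] <- flat[, c]
  df$label <- rep(ws$labels, each = T)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %.10g", ws$sampling_rate), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a window set from CSV
#'
#' @param path CSV path written by [write_windowset_csv()].
#' @return A `window_set`.
#' @export
read_windowset_csv <- function(path) {
  first <- readLines(path, n = 1)
  sampling_rate <- NA_real_
  if (grepl("^# sampling_rate:", first)) {
    sampling_rate <- as.numeric(sub("^# sampling_rate:", "", first))
    df <- utils::read.csv(path, skip = 1)
  } else df <- utils::read.csv(path)
  chans <- setdiff(names(df), c("window", "t", "label"))
  wins <- sort(unique(df$window))
  T <- max(df$t) + 1L
  N <- length(wins); C <- length(chans)
  data <- array(0, dim = c(N, T, C))
  labels <- integer(N)
  df <- df[order(df$window, df$t), ]
  flat <- as.matrix(df[chans])
  data[] <- aperm(array(flat, dim = c(T, N, C)), c(2, 1, 3))
  labels <- as.integer(df$label[df$t == 0])
  new_window_set(data, labels, NA_integer_, sampling_rate, chans)
}

#' Serialise a feature database to JSON
#'
#' @param db A `feature_db`.
#' @param path Output JSON path.
#' @export
write_feature_db <- function(db, path) {
  stopifnot(inherits(db, "feature_db"))
  out <- list(feature_dim = db$feature_dim, method = db$method,
              tau_new = db$tau_new,
              classes = lapply(db$classes, function(e)
                list(seeds = unname(as.matrix(e$seeds)), tau = e$tau,
                     predefined = e$predefined)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature database from JSON
#'
#' @param path JSON path written by [write_feature_db()].
#' @return A `feature_db`.
#' @export
read_feature_db <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  db <- feature_db(x$feature_dim, x$method)
  db$tau_new <- if (is.null(x$tau_new)) NA_real_ else x$tau_new
  db$classes <- lapply(x$classes, function(e)
    list(seeds = matrix(e$seeds, ncol = x$feature_dim), tau = e$tau,
         predefined = isTRUE(e$predefined)))
  names(db$classes) <- names(x$classes)
  db
}

#' Save / load a trained model
#'
#' Single-file binary container (RDS); the architecture configuration is also
#' written to a JSON sidecar `<path>.json` for inspection.
#'
#' @param model A `marginhar_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "marginhar_model"))
  saveRDS(model, path)
  side <- list(kind = model$cfg$kind, head = model$head$kind,
               input_shape = as.list(model$input_shape),
               n_classes = model$n_classes,
               feature_dim = model$feature_dim,
               scale = model$cfg$scale, margin = model$cfg$margin,
               trained = model$trained)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "marginhar_model"))
  model
}
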