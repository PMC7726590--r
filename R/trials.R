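#' Trial-level continuous-report data
#'
#' Datasets are plain data frames (tibbles) with one row per trial. 2D data
#' use the columns `resp_x`, `resp_y`, `targ_x`, `targ_y` and then repeated
#' `nt{i}_x`, `nt{i}_y` (optionally `nt{i}_class`) triples for the
#' nontargets; an optional `condition` column labels conditions. The number
#' of nontargets may vary across trials: absent nontargets are `NA`. 1D
#' (circular) data use `resp`, `targ` and `nt{i}` columns holding angles in
#' radians, reduced to `[-pi, pi)`.
#'
#' @name trial-data
NULL

## Extract the numeric structure of a 2D dataset once, for vectorised
## density evaluation: response/target matrices plus nontarget coordinate
## matrices padded with NA, per-trial nontarget counts, and class labels.
trial_matrices <- function(data) {
  need <- c("resp_x", "resp_y", "targ_x", "targ_y")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing mandatory columns: ", paste(miss, collapse = ", "))
  nt_idx <- sort(as.integer(sub("^nt([0-9]+)_x$", "\\1",
                                grep("^nt[0-9]+_x$", names(data), value = TRUE))))
  n <- nrow(data)
  resp <- cbind(data$resp_x, data$resp_y)
  targ <- cbind(data$targ_x, data$targ_y)
  if (length(nt_idx)) {
    ntx <- sapply(nt_idx, function(i) as.numeric(data[[paste0("nt", i, "_x")]]))
    nty <- sapply(nt_idx, function(i) as.numeric(data[[paste0("nt", i, "_y")]]))
    ntx <- matrix(ntx, nrow = n); nty <- matrix(nty, nrow = n)
    cls <- sapply(nt_idx, function(i) {
      col <- paste0("nt", i, "_class")
      if (col %in% names(data)) as.numeric(data[[col]]) else rep(NA_real_, n)
    })
    cls <- matrix(cls, nrow = n)
    m <- rowSums(!is.na(ntx) & !is.na(nty))
  } else {
    ntx <- nty <- cls <- matrix(numeric(0), nrow = n, ncol = 0)
    m <- rep(0L, n)
  }
  list(resp = resp, targ = targ, ntx = ntx, nty = nty, class = cls,
       m = as.numeric(m), n = n)
}

trial_matrices_1d <- function(data) {
  need <- c("resp", "targ")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("1D dataset is missing mandatory columns: ",
         paste(miss, collapse = ", "))
  nt_idx <- sort(as.integer(sub("^nt([0-9]+)$", "\\1",
                                grep("^nt[0-9]+$", names(data), value = TRUE))))
  n <- nrow(data)
  nt <- if (length(nt_idx))
    matrix(sapply(nt_idx, function(i) as.numeric(data[[paste0("nt", i)]])),
           nrow = n)
  else matrix(numeric(0), nrow = n, ncol = 0)
  list(resp = as.numeric(data$resp), targ = as.numeric(data$targ), nt = nt,
       m = as.numeric(rowSums(!is.na(nt))), n = n)
}

#' Reduce angles to the circular domain
#'
#' @param theta Angles in radians.
#' @return Angles wrapped to `[-pi, pi)`.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out
}

#' Read and write trial-level CSV files
#'
#' `read_trials()` reads a continuous-report dataset (see [trial-data] for
#' the column contract), validates coordinates against the screen and drops
#' rows whose response, target or nontarget coordinates lie off-screen,
#' warning with the offending row numbers. `write_trials()` writes a dataset
#' in the same format.
#'
#' @param path File path.
#' @param screen A [screen_geometry()].
#' @param data Data frame of trials.
#' @return `read_trials()` returns a tibble of validated trials.
#' @export
read_trials <- function(path, screen = screen_geometry()) {
  screen <- as_screen(screen)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0) stop("no data rows in ", path)
  tm <- trial_matrices(data)
  coord_cols <- grep("^(resp|targ|nt[0-9]+)_[xy]$", names(data), value = TRUE)
  for (col in coord_cols)
    if (!is.numeric(data[[col]]))
      stop("non-numeric coordinates in column ", col)
  bad <- !on_screen(tm$resp, screen) | !on_screen(tm$targ, screen)
  if (ncol(tm$ntx))
    bad <- bad | rowSums((!is.na(tm$ntx)) &
                           (tm$ntx < 0 | tm$ntx > screen$width |
                              tm$nty < 0 | tm$nty > screen$height)) > 0
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with off-screen coordinates: ",
            paste(which(bad), collapse = ", "))
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) == 0) stop("no valid trials remain after validation")
  tibble::as_tibble(data)
}

#' @rdname read_trials
#' @export
write_trials <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
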