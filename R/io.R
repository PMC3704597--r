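#' Write trials to the long-format trajectory CSV
#'
#' One row per frame x marker with header
#' \code{subject,condition,trial,frame,marker,x,y,z}; per-trial force traces
#' (if present) are written alongside as
#' \code{force_<subject>_<condition>_<trial>.csv} with header
#' \code{frame,fz_newton}.
#'
#' @param trials list of \linkS4class{TrialRecord}.
#' @param file CSV path for the trajectories.
#' @param forceDir optional directory for the force CSVs.
#' @export
writeTrialsLong <- function(trials, file, forceDir = NULL) {
  rows <- lapply(trials, function(tr) {
    d <- dim(tr@positions)
    g <- expand.grid(frame = seq_len(d[1L]), marker = seq_len(d[2L]))
    data.frame(subject = tr@subject, condition = tr@condition,
               trial = tr@trial, frame = g$frame, marker = g$marker,
               x = as.vector(tr@positions[, , 1L]),
               y = as.vector(tr@positions[, , 2L]),
               z = as.vector(tr@positions[, , 3L]))
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE, quote = FALSE)
  if (!is.null(forceDir)) {
    dir.create(forceDir, showWarnings = FALSE, recursive = TRUE)
    for (tr in trials) {
      if (length(tr@force) == 0L) next
      fn <- file.path(forceDir, sprintf("force_%s_%s_%d.csv", tr@subject,
                                        tr@condition, tr@trial))
      write.csv(data.frame(frame = seq_along(tr@force),
                           fz_newton = tr@force), fn,
                row.names = FALSE, quote = FALSE)
    }
  }
  invisible(file)
}

#' Read trials from the long-format trajectory CSV
#'
#' @param file CSV with header
#'   \code{subject,condition,trial,frame,marker,x,y,z}.
#' @param forceDir optional directory holding the matching force CSVs (see
#'   [writeTrialsLong()]).
#' @param sampleRate sampling rate in Hz to stamp on the trials.
#' @return list of \linkS4class{TrialRecord}.
#' @export
readTrialsLong <- function(file, forceDir = NULL, sampleRate = 240) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "trial", "frame", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("long-format CSV must have columns ", paste(need, collapse = ","))
  key <- interaction(df$subject, df$condition, df$trial, drop = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$marker, g$frame), ]
    nf <- length(unique(g$frame))
    nm <- length(unique(g$marker))
    if (nrow(g) != nf * nm)
      stop("incomplete frame x marker grid for subject=", g$subject[1L],
           " condition=", g$condition[1L], " trial=", g$trial[1L])
    pos <- array(c(g$x, g$y, g$z), dim = c(nf, nm, 3L))
    force <- numeric(0)
    if (!is.null(forceDir)) {
      fn <- file.path(forceDir, sprintf("force_%s_%s_%d.csv", g$subject[1L],
                                        g$condition[1L], g$trial[1L]))
      if (file.exists(fn)) force <- read.csv(fn)$fz_newton
    }
    TrialRecord(subject = g$subject[1L], condition = g$condition[1L],
                trial = g$trial[1L], positions = pos,
                sampleRate = sampleRate, force = force)
  })
}

#' Write the assembled matrix in the exchange format
#'
#' A headerless numeric CSV (one row per trial) plus a JSON sidecar holding
#' the ordered trial keys, the layout parameters, the whitening flag and --
#' when whitened -- the per-subject statistics.
#'
#' @param x a \linkS4class{KinematicExperiment}.
#' @param file CSV path; the sidecar is written to \code{<file>.json}.
#' @export
writeAssembledMatrix <- function(x, file) {
  M <- trialMatrix(x)
  utils::write.table(M, file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  cd <- as.data.frame(trialInfo(x))
  st <- subjectStats(x)
  side <- list(row_meta = cd,
               layout = list(markers = x@layout@markers,
                             axes = x@layout@axes,
                             timepoints = x@layout@timepoints,
                             one_based = TRUE),
               whitened = isWhitened(x),
               subject_stats = if (length(st))
                 list(subjects = as.list(colnames(st$mean)),
                      mean = as.list(as.data.frame(st$mean)),
                      sd = as.list(as.data.frame(st$sd)),
                      degenerate = as.list(st$degenerate))
                 else NULL)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read the assembled matrix from the exchange format
#'
#' @param file CSV path written by [writeAssembledMatrix()] (expects the
#'   \code{<file>.json} sidecar next to it).
#' @return a \linkS4class{KinematicExperiment}.
#' @export
readAssembledMatrix <- function(file) {
  M <- as.matrix(read.csv(file, header = FALSE))
  dimnames(M) <- NULL
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = FALSE)
  lay <- KinematicLayout(side$layout$markers, side$layout$axes,
                         side$layout$timepoints)
  rm <- side$row_meta
  cd <- S4Vectors::DataFrame(
    subject = vapply(rm, function(r) as.character(r$subject), ""),
    condition = vapply(rm, function(r) as.character(r$condition), ""),
    trial = vapply(rm, function(r) as.integer(r$trial), 1L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(positions = t(M)), colData = cd)
  stats <- list()
  if (isTRUE(side$whitened)) {
    subj <- vapply(side$subject_stats$subjects, as.character, "")
    asMat <- function(lst) {
      m <- do.call(cbind, lapply(lst, function(v) vapply(v, as.numeric, 1)))
      colnames(m) <- subj
      m
    }
    stats <- list(mean = asMat(side$subject_stats$mean),
                  sd = asMat(side$subject_stats$sd),
                  degenerate = vapply(side$subject_stats$degenerate,
                                      as.integer, 1L))
  }
  new("KinematicExperiment", se, layout = lay,
      whitened = isTRUE(side$whitened), subjectStats = stats)
}
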