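#' Labeled epoched EEG trials
#'
#' @description
#' The trial container used throughout the package: a set of epoched,
#' same-length, multichannel EEG trials with class labels. The canonical
#' geometry (matching the packaged 22-channel montage) is 22 channels,
#' 4-second epochs at 250 Hz, hence 1000 samples per channel; other
#' geometries are accepted as long as they are internally consistent.
#'
#' @param signals numeric array `trials x channels x samples` (microvolts).
#' @param labels per-trial class label; coerced to a factor. If `class_names`
#'   is given it is used as the level set.
#' @param fs sampling rate in Hz.
#' @param channel_names ordered channel names, length `dim(signals)[2]`. The
#'   order must match the electrode layout used to build any structural
#'   graph applied to these trials.
#' @param subject_ids optional per-trial integer subject id.
#' @param class_names optional ordered class names (factor levels).
#' @param provenance optional named list recording how the trials were made
#'   (generator spec, filters, embedding).
#' @return An object of class `trial_set`.
#' @examples
#' x <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
#' ts <- trial_set(x, labels = c("a", "b"), fs = 10,
#'                 channel_names = c("c1", "c2", "c3"))
#' dim(ts)
#' @export
trial_set <- function(signals, labels, fs, channel_names,
                      subject_ids = NULL, class_names = NULL,
                      provenance = list()) {
  stopifnot(is.array(signals), length(dim(signals)) == 3L)
  n <- dim(signals)[1]
  if (length(labels) != n)
    stop("length(labels) != number of trials", call. = FALSE)
  if (length(channel_names) != dim(signals)[2])
    stop("length(channel_names) != number of channels", call. = FALSE)
  if (is.null(class_names)) {
    labels <- as.factor(labels)
  } else {
    labels <- factor(labels, levels = class_names)
    if (anyNA(labels)) stop("labels outside class_names", call. = FALSE)
  }
  if (!is.null(subject_ids) && length(subject_ids) != n)
    stop("length(subject_ids) != number of trials", call. = FALSE)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  dimnames(signals) <- list(NULL, channel_names, NULL)
  structure(
    list(signals = signals, labels = labels, fs = fs,
         channel_names = as.character(channel_names),
         subject_ids = subject_ids,
         provenance = provenance),
    class = "trial_set")
}

#' @export
dim.trial_set <- function(x) dim(x$signals)

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat("<trial_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  classes: ", paste(levels(x$labels), collapse = ", "), "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
`[.trial_set` <- function(x, i) {
  trial_set(x$signals[i, , , drop = FALSE], x$labels[i], x$fs,
            x$channel_names,
            subject_ids = if (!is.null(x$subject_ids)) x$subject_ids[i],
            class_names = levels(x$labels),
            provenance = x$provenance)
}

#' Per-trial amplitude standardization
#'
#' @description
#' Standardizes each trial independently (so no statistic ever crosses a
#' cross-validation fold boundary). `method = "global"` (the default used
#' before the structural embedding) centres and scales each trial with a
#' single mean and standard deviation pooled over all channels, preserving
#' the relative power topography across channels — the carrier of
#' event-related (de)synchronization effects. `method = "channel"` scales
#' every channel to unit variance, which equalizes channel power and is only
#' appropriate when the classifier should ignore the power topography.
#' `method = "none"` returns the input unchanged (useful for exact-arithmetic
#' tests).
#'
#' @param trials a `trial_set`.
#' @param method `"global"`, `"channel"` or `"none"`.
#' @return A `trial_set` with standardized signals.
#' @export
scale_trials <- function(trials, method = c("global", "channel", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(trials, "trial_set"))
  if (method == "none") return(trials)
  x <- trials$signals
  n <- dim(x)[1]
  for (t in seq_len(n)) {
    m <- x[t, , , drop = FALSE]
    if (method == "global") {
      x[t, , ] <- (m - mean(m)) / (stats::sd(m) + 1e-12)
    } else {
      mu <- apply(m[1, , , drop = TRUE], 1, mean)
      sg <- apply(m[1, , , drop = TRUE], 1, stats::sd)
      x[t, , ] <- (m[1, , ] - mu) / (sg + 1e-12)
    }
  }
  out <- trials
  out$signals <- x
  out$provenance$scaling <- method
  out
}

# container format version; bump on layout changes
.container_version <- "graphmi-container-1"

#' Read and write the trial container
#'
#' @description
#' `write_container()` serializes a `trial_set` (or an embedded set / PLV
#' tensor, which reuse the same mechanism) to a single versioned file;
#' `read_container()` restores it losslessly. The container embeds the
#' provenance list — generator spec, filters applied, the checksum of any
#' normalized adjacency used for embedding — so a stored dataset documents
#' its own preprocessing. Files are written with R's native serialization
#' and are intended as workflow artifacts, not an interchange format; use
#' [write_matrix_csv()] for portable matrix export.
#'
#' @param trials object to store.
#' @param path file path.
#' @param expect_channels optional channel names the caller requires; a
#'   mismatch is an error (guards against pairing a dataset with the wrong
#'   montage).
#' @return `read_container()` returns the stored object; `write_container()`
#'   returns `path` invisibly.
#' @export
write_container <- function(trials, path) {
  payload <- list(version = .container_version, object = trials)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path, expect_channels = NULL) {
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$version))
    stop("not a graphmi container: ", path, call. = FALSE)
  if (!identical(payload$version, .container_version))
    stop("container version mismatch: found '", payload$version,
         "', expected '", .container_version, "'", call. = FALSE)
  obj <- payload$object
  if (!is.null(expect_channels)) {
    ch <- obj$channel_names
    if (!identical(as.character(ch), as.character(expect_channels)))
      stop("channel mismatch: container has ", length(ch),
           " channels [", paste(utils::head(ch, 3), collapse = ", "),
           ", ...]; expected ", length(expect_channels), call. = FALSE)
  }
  obj
}

#' Epoch window in sample indices
#'
#' Converts a half-open time window `[start, end)` in seconds (relative to
#' trial start) into 1-based sample indices at rate `fs`. The default window
#' `[2, 6)` extracts the 4-s task period that begins at the cue (t = 2 s).
#'
#' @param window numeric length-2, seconds.
#' @param fs sampling rate, Hz.
#' @return Integer vector of sample indices.
#' @export
epoch_window_samples <- function(window = c(2, 6), fs = 250) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  i0 <- floor(window[1] * fs)          # 0-based first sample
  i1 <- floor(window[2] * fs)          # 0-based one-past-last
  seq.int(i0 + 1L, i1)                 # 1-based, half-open => length (end-start)*fs
}

#' Ingest a 22-channel motor-imagery recording set (optional)
#'
#' @description
#' Loads user-supplied GDF recordings of the standard 22-channel,
#' 250 Hz four-class motor-imagery benchmark into a [trial_set()]: EOG
#' channels are dropped, and per-trial epochs are cut with
#' [epoch_window_samples()] (default `[2, 6)` s, i.e. the 4-s task period
#' following the cue). The data are never downloaded by the package; GDF
#' decoding is delegated to the `mne` Python library when a `python`
#' interpreter with `mne` is on the `PATH`. Without it (or without the
#' files) this function stops with instructions — the rest of the package,
#' including every test, runs on synthetic data only.
#'
#' @param directory directory containing `A0xT.gdf` files and matching
#'   `A0xT_labels.csv` (one integer label 1-4 per trial) if the GDF events
#'   lack class codes.
#' @param epoch_window time window in seconds, see [epoch_window_samples()].
#' @param subjects integer vector of subject numbers to load (default 1:9).
#' @return A `trial_set` with class names
#'   `c("left_hand", "right_hand", "feet", "tongue")`.
#' @export
ingest_bci2a <- function(directory, epoch_window = c(2, 6), subjects = 1:9) {
  if (!dir.exists(directory))
    stop("directory not found: ", directory,
         "\nSupply the GDF recordings yourself (files A01T.gdf ... A09T.gdf); ",
         "this package never downloads data.", call. = FALSE)
  files <- file.path(directory, sprintf("A%02dT.gdf", subjects))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing recordings: ", paste(basename(missing), collapse = ", "),
         "\nPlace the session-1 GDF files in ", directory, ".", call. = FALSE)
  if (Sys.which("python") == "")
    stop("GDF ingest needs a 'python' interpreter with the 'mne' package on the PATH",
         call. = FALSE)
  helper <- system.file("cli", "gdf_to_csv.py", package = "graphmi", mustWork = TRUE)
  idx <- epoch_window_samples(epoch_window, fs = 250)
  sigs <- NULL; labels <- integer(0); subj <- integer(0); chn <- NULL
  for (s in seq_along(subjects)) {
    out <- tempfile(fileext = ".csv")
    status <- system2("python", c(helper, shQuote(files[s]), shQuote(out),
                                  epoch_window[1], epoch_window[2]),
                      stdout = FALSE)
    if (status != 0)
      stop("GDF decoding failed for ", basename(files[s]),
           " (is python-mne installed?)", call. = FALSE)
    tab <- utils::read.csv(out, check.names = FALSE)
    # long format: trial, label, channel columns; one row per sample
    chn0 <- setdiff(colnames(tab), c("trial", "label"))
    ntr <- length(unique(tab$trial))
    m <- length(idx)
    a <- array(NA_real_, c(ntr, length(chn0), m))
    lab <- integer(ntr)
    for (tr in seq_len(ntr)) {
      rows <- tab$trial == tr - 1L
      a[tr, , ] <- t(as.matrix(tab[rows, chn0]))
      lab[tr] <- tab$label[rows][1]
    }
    sigs <- if (is.null(sigs)) a else {
      stopifnot(identical(chn, chn0))
      abind_first(sigs, a)
    }
    chn <- chn0
    labels <- c(labels, lab)
    subj <- c(subj, rep.int(subjects[s], ntr))
  }
  trial_set(sigs, labels = c("left_hand", "right_hand", "feet", "tongue")[labels],
            fs = 250, channel_names = chn, subject_ids = subj,
            class_names = c("left_hand", "right_hand", "feet", "tongue"),
            provenance = list(source = "bci2a", epoch_window = epoch_window))
}

# bind two trials x channels x samples arrays along the first axis
abind_first <- function(a, b) {
  stopifnot(identical(dim(a)[-1], dim(b)[-1]))
  out <- array(NA_real_, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
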