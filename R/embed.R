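#' Structural graph embedding of epoched trials
#'
#' @description
#' Applies the structural embedding \eqn{G = \hat A X} to every trial:
#' each trial's `channels x samples` matrix is premultiplied by the
#' normalized adjacency \eqn{\hat A} of the montage graph, so every channel
#' is replaced by the degree-weighted average of itself and its grid
#' neighbours. The operation is linear, shape-preserving, and local — output
#' channel *i* depends only on channel *i* and its graph neighbours.
#'
#' By default trials are standardized first with [scale_trials()]
#' (`method = "global"`), which stabilizes network training on raw-microvolt
#' recordings while preserving the cross-channel power topography; pass
#' `scale = "none"` for exact-arithmetic checks.
#'
#' @param trials a `trial_set` whose channel order equals the graph layout
#'   order.
#' @param graph a `structural_graph` from [build_adjacency()].
#' @param scale input standardization, see [scale_trials()].
#' @return An object of class `embedded_trial_set` (it is also a valid
#'   `trial_set`): signals hold the embedded trials; the provenance records
#'   the scaling and a checksum of the \eqn{\hat A} used.
#' @examples
#' g <- build_adjacency(build_layout("bci2a"))
#' x <- array(rnorm(2 * 22 * 50), c(2, 22, 50))
#' ts <- trial_set(x, c("a", "b"), fs = 250, channel_names = g$layout$channels)
#' emb <- embed_trials(ts, g, scale = "none")
#' dim(emb)
#' @export
embed_trials <- function(trials, graph,
                         scale = c("global", "channel", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(trials, "trial_set"), inherits(graph, "structural_graph"))
  lay_ch <- graph$layout$channels
  if (!identical(trials$channel_names, lay_ch)) {
    bad <- which(trials$channel_names != lay_ch)[1]
    if (is.na(bad))
      stop("trial set has ", length(trials$channel_names),
           " channels but the graph layout has ", length(lay_ch), call. = FALSE)
    stop("channel order mismatch at position ", bad, ": trials have '",
         trials$channel_names[bad], "', layout expects '", lay_ch[bad], "'",
         call. = FALSE)
  }
  trials <- scale_trials(trials, scale)
  x <- trials$signals
  d <- dim(x)
  A_hat <- graph$A_hat
  storage.mode(x) <- "double"
  for (t in seq_len(d[1]))
    x[t, , ] <- A_hat %*% x[t, , ]
  out <- trials
  out$signals <- x
  out$provenance$embedding <- list(
    kind = "structural_adjacency",
    a_hat_checksum = a_hat_checksum(A_hat))
  class(out) <- c("embedded_trial_set", "trial_set")
  out
}

# order-stable checksum of the normalized adjacency, for provenance
a_hat_checksum <- function(A_hat) {
  v <- sprintf("%.12g", round(as.numeric(A_hat), 12))
  sum_ <- sum(utf8ToInt(paste(v, collapse = ",")) *
                (seq_along(utf8ToInt(paste(v, collapse = ",")))%%97 + 1))
  sprintf("%x-%d", sum_ %% 2^28, nrow(A_hat))
}

#' @export
print.embedded_trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat("<embedded_trial_set> ", d[1], " trials x ", d[2], " channels x ",
      d[3], " samples (structural embedding applied)\n", sep = "")
  invisible(x)
}
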