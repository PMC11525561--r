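#' Distance time series for one residue pair
#'
#' @param times numeric, timestamps in ns.
#' @param values numeric, per-frame distances (all > 0 for real pairs; 0 is
#'   tolerated for degenerate synthetic frames).
#' @param unit `"nm"` or `"angstrom"`.
#' @param pair_label e.g. `"CYS50-ASN65"`.
#' @param replicate_id replicate tag.
#' @return object of class `distance_series`.
#' @export
distance_series_new <- function(times, values, unit = "nm", pair_label = "",
                                replicate_id = "") {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(!is.finite(values)) || any(values < 0))
    stop("distances must be finite and non-negative")
  unit <- match.arg(unit, c("nm", "angstrom"))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, pair_label = pair_label,
                 replicate_id = replicate_id),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s%s: %d frames, mean %.4f %s\n",
              x$pair_label,
              if (nzchar(x$replicate_id)) paste0(" [", x$replicate_id, "]") else "",
              length(x$values), mean(x$values), x$unit))
  invisible(x)
}

#' Per-frame residue-pair alpha-carbon distance
#'
#' Plain Euclidean distance between the CA atoms of two residues in every
#' frame. (For single-atom groups this equals the minimum group distance
#' that MD tools such as gmx mindist report.) Coordinates are stored in
#' Angstrom; the reporting unit is configurable, defaulting to nm, the
#' customary MD unit.
#'
#' @param frames a [trajectory_frames] object.
#' @param residue_a,residue_b residue sequence numbers (default 50 and 65,
#'   the CYS50-ASN65 membrane-binding-domain pair).
#' @param chain_a,chain_b optional chains, passed to [get_alpha_carbon()].
#' @param unit reporting unit, `"nm"` (default) or `"angstrom"`.
#' @param replicate_id replicate tag stored on the series (defaults to the
#'   trajectory's source label).
#' @return a [distance_series_new] object.
#' @export
distance_series <- function(frames, residue_a = 50L, residue_b = 65L,
                            chain_a = NULL, chain_b = NULL,
                            unit = c("nm", "angstrom"),
                            replicate_id = NULL) {
  unit <- match.arg(unit)
  ca <- get_alpha_carbon(frames, residue_a, chain_a)
  cb <- get_alpha_carbon(frames, residue_b, chain_b)
  d_ang <- sqrt(rowSums((ca - cb)^2))
  d <- if (unit == "nm") d_ang / 10 else d_ang
  a <- frames$atoms
  lab <- function(rn) {
    nm <- a$resname[a$atom == "CA" & a$resno == rn][1L]
    paste0(nm, rn)
  }
  distance_series_new(
    times = frames$times, values = d, unit = unit,
    pair_label = paste0(lab(residue_a), "-", lab(residue_b)),
    replicate_id = if (is.null(replicate_id)) frames$source_label else replicate_id
  )
}

#' Select a half-open time window of a distance series
#'
#' Frames with `t_start <= t < t_end` are retained. Pass `t_end = "end"` to
#' include the final frame (internally the last timestamp plus a small
#' epsilon). `t_start = "half"` selects the last half of the time span, the
#' protocol used for replicate production runs (last 100 ns of 200 ns).
#'
#' @param series a distance series.
#' @param t_start window start in ns, or `"half"`.
#' @param t_end window end in ns, or `"end"`.
#' @return the windowed distance series.
#' @export
window_select <- function(series, t_start, t_end = "end") {
  stopifnot(inherits(series, "distance_series"))
  tspan <- range(series$times)
  if (identical(t_start, "half")) t_start <- tspan[1L] + diff(tspan) / 2
  if (identical(t_end, "end")) t_end <- tspan[2L] + 1e-9 * max(1, abs(tspan[2L]))
  if (!(t_start < t_end)) stop("t_start must be < t_end")
  keep <- series$times >= t_start & series$times < t_end
  if (!any(keep))
    stop(sprintf("window [%g, %g) selects no frames; series spans [%g, %g] ns",
                 t_start, t_end, tspan[1L], tspan[2L]))
  distance_series_new(series$times[keep], series$values[keep],
                      unit = series$unit, pair_label = series$pair_label,
                      replicate_id = series$replicate_id)
}

new_replicate_summary <- function(member_means, window, unit, pair_label,
                                  kind) {
  n <- length(member_means)
  structure(list(mean = mean(member_means),
                 sem = stats::sd(member_means) / sqrt(n),
                 n = n, member_means = as.numeric(member_means),
                 window = window, unit = unit, pair_label = pair_label,
                 kind = kind),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> %s: %.4f +/- %.4f %s (n = %d %s)\n",
              x$pair_label, x$mean, x$sem, x$unit, x$n,
              if (x$kind == "block") "blocks" else "replicates"))
  invisible(x)
}

#' Block-average summary of one long series
#'
#' Splits the series into `n_blocks` contiguous blocks of equal frame count
#' (remainder frames are assigned to the final block), and reports the mean
#' of the block means with its standard error, `sd(block means)/sqrt(n)`
#' (sample SD, n-1 denominator). Block averaging is the standard way to get
#' an honest SEM from an autocorrelated MD series: with blocks longer than
#' the correlation time the block means are nearly independent. The
#' reference protocol splits a 1 us run into ten 100 ns blocks.
#'
#' @param series a distance series.
#' @param n_blocks number of blocks (>= 2, <= frame count; default 10).
#' @return a `replicate_summary`.
#' @export
block_summary <- function(series, n_blocks = 10L) {
  stopifnot(inherits(series, "distance_series"))
  nv <- length(series$values)
  if (n_blocks < 2L) stop("n_blocks must be >= 2")
  if (n_blocks > nv)
    stop(sprintf("n_blocks (%d) exceeds the frame count (%d)", n_blocks, nv))
  per <- nv %/% n_blocks
  starts <- (seq_len(n_blocks) - 1L) * per + 1L
  ends <- c(starts[-1L] - 1L, nv)  # remainder goes to the last block
  member_means <- vapply(seq_len(n_blocks),
                         function(b) mean(series$values[starts[b]:ends[b]]),
                         numeric(1L))
  new_replicate_summary(member_means, window = range(series$times),
                        unit = series$unit, pair_label = series$pair_label,
                        kind = "block")
}

#' Across-replicate summary of windowed series
#'
#' For each replicate series, the values inside the analysis window are
#' averaged; the summary is the mean of those per-replicate means with SEM
#' across replicates. This is the protocol for replicate production runs:
#' five 200 ns replicates, last 100 ns analysed, mean and SEM across the
#' five window means.
#'
#' @param series_list list of distance series (>= 2), one per replicate.
#' @param window length-2 numeric `c(t_start, t_end)` in ns, or `"last_half"`
#'   (default) for the second half of each replicate's time span.
#' @return a `replicate_summary`.
#' @export
replicate_summary <- function(series_list, window = "last_half") {
  if (length(series_list) < 2L) stop("need >= 2 replicate series")
  units <- unique(vapply(series_list, `[[`, character(1L), "unit"))
  if (length(units) != 1L) stop("replicates carry mixed distance units: ",
                                paste(units, collapse = ", "))
  member_means <- vapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    w <- tryCatch({
      if (identical(window, "last_half")) window_select(s, "half", "end")
      else window_select(s, window[1L], window[2L])
    }, error = function(e) {
      stop(sprintf("replicate '%s': %s",
                   if (nzchar(s$replicate_id)) s$replicate_id else as.character(i),
                   conditionMessage(e)), call. = FALSE)
    })
    mean(w$values)
  }, numeric(1L))
  win <- if (identical(window, "last_half")) c(NA_real_, NA_real_) else as.numeric(window)
  new_replicate_summary(member_means, window = win, unit = units,
                        pair_label = series_list[[1L]]$pair_label,
                        kind = "replicate")
}

#' Tabulate one or more replicate summaries
#'
#' @param summaries a `replicate_summary` or list of them.
#' @param labels optional character labels (e.g. compound ids).
#' @return data.frame with columns pair_label, n, mean, sem, unit, window
#'   and the member means serialized as a JSON list column.
#' @export
summary_table <- function(summaries, labels = NULL) {
  if (inherits(summaries, "replicate_summary")) summaries <- list(summaries)
  rows <- lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(
      label = if (is.null(labels)) names(summaries)[i] %||% "" else labels[i],
      pair_label = s$pair_label, n = s$n, mean = s$mean, sem = s$sem,
      unit = s$unit,
      window = paste(signif(s$window, 8), collapse = ".."),
      member_means = as.character(jsonlite::toJSON(s$member_means, digits = NA)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
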