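# Activity-intensity classification of 1-s VM3 count series against
# counts-per-minute cut-points, by back-to-back 60-s epochs (discrete) or a
# per-second sliding 60-s window (continuous).

#' Intensity cut-point scale
#'
#' An ordered set of intensity categories, each defined by a lower bound in
#' counts per minute. Category k covers the half-open interval
#' `[lower_k, lower_{k+1})`; the last category is unbounded above.
#'
#' @param name scale name.
#' @param categories data frame with columns `name` (unique) and `lower`
#'   (strictly increasing, first element 0).
#' @return An object of class `cutpoint_scale`.
#' @seealso [freedson_vm3()]
#' @export
cutpoint_scale <- function(name, categories) {
  categories <- as.data.frame(categories)
  if (!all(c("name", "lower") %in% names(categories)))
    stop_invalid("categories must have columns 'name' and 'lower'")
  categories$name <- as.character(categories$name)
  categories$lower <- as.numeric(categories$lower)
  if (nrow(categories) < 1L || categories$lower[1] != 0)
    stop_invalid("the first category's lower bound must be 0")
  if (nrow(categories) > 1L && any(diff(categories$lower) <= 0))
    stop_invalid("lower bounds must be strictly increasing")
  if (anyDuplicated(categories$name))
    stop_invalid("category names must be unique")
  structure(list(name = name, categories = categories),
            class = "cutpoint_scale")
}

#' @export
print.cutpoint_scale <- function(x, ...) {
  cat("Cut-point scale:", x$name, "\n")
  up <- c(x$categories$lower[-1], Inf)
  for (i in seq_len(nrow(x$categories)))
    cat(sprintf("  %-14s [%g, %g) counts/min\n", x$categories$name[i],
                x$categories$lower[i], up[i]))
  invisible(x)
}

#' Freedson Adult VM3 cut-points
#'
#' The default scale: Light `[0, 2960)`, Moderate `[2960, 6167)`, Vigorous
#' `[6167, 9643)`, Very vigorous `[9643, Inf)` counts per minute. The
#' published cut-points are integers (Light < 2960, Moderate 2960-6166,
#' Vigorous 6167-9642, Very vigorous > 9642); the half-open intervals encode
#' them exactly while also placing the non-integer counts-per-minute values
#' produced by rescaled boundary windows.
#'
#' @return A [cutpoint_scale()].
#' @export
freedson_vm3 <- function() {
  cutpoint_scale("Freedson Adult VM3",
                 data.frame(name = c("Light", "Moderate", "Vigorous",
                                     "Very vigorous"),
                            lower = c(0, 2960, 6167, 9643)))
}

#' Classify a counts-per-minute value
#'
#' @param cpm nonnegative counts per minute (vectorized).
#' @param scale a [cutpoint_scale()].
#' @return Character vector of category names.
#' @export
classify_epoch <- function(cpm, scale = freedson_vm3()) {
  stopifnot(inherits(scale, "cutpoint_scale"))
  cpm <- as.numeric(cpm)
  if (any(cpm < 0)) stop_invalid("counts per minute must be nonnegative")
  idx <- findInterval(cpm, scale$categories$lower)
  scale$categories$name[idx]
}

new_intensity_profile <- function(scale, categories, method, epoch_total,
                                  detail, incomplete = FALSE) {
  tab <- table(factor(categories, levels = scale$categories$name))
  epochs <- as.integer(tab)
  pct <- if (epoch_total > 0) 100 * epochs / epoch_total else
    rep(0, length(epochs))
  structure(list(scale = scale$name,
                 summary = data.frame(category = scale$categories$name,
                                      epochs = epochs, percent = pct),
                 detail = detail, method = method,
                 epoch_total = as.integer(epoch_total),
                 incomplete = incomplete),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("Intensity profile (", x$method, " method, ", x$epoch_total,
      " epochs, scale: ", x$scale, ")\n", sep = "")
  if (x$incomplete) cat("  [series shorter than one minute: empty profile]\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-14s %6d epochs  %6.2f %%\n", x$summary$category[i],
                x$summary$epochs[i], x$summary$percent[i]))
  invisible(x)
}

# extract a 1-s VM3 vector from a count_series or numeric vector
vm3_per_second <- function(counts) {
  if (inherits(counts, "count_series")) {
    if (!isTRUE(all.equal(counts$epoch_s, 1)))
      stop_invalid("classification requires 1-s epochs; got epoch_s = ",
                   counts$epoch_s)
    counts$vm3
  } else as.numeric(counts)
}

#' Discrete activity-intensity classification
#'
#' Partitions a 1-s VM3 count series into back-to-back 60-s epochs starting
#' at the first second; each epoch's counts-per-minute value is the sum of
#' its 60 one-second counts, classified against the scale. A trailing
#' partial minute is dropped. A 3-min series therefore yields exactly three
#' epochs — and the resulting percentages depend on how activity bouts align
#' with the epoch grid (the phase sensitivity the continuous method removes).
#'
#' @param counts a [count_series()] at 1-s epochs, or a numeric vector of
#'   1-s VM3 counts.
#' @param scale a [cutpoint_scale()]; default [freedson_vm3()].
#' @return An `intensity_profile` with a per-epoch `detail` data frame
#'   (`index`, `cpm`, `category`). For series shorter than 60 s an empty
#'   profile is returned with `incomplete = TRUE` and a warning.
#' @export
discrete_classification <- function(counts, scale = freedson_vm3()) {
  v <- vm3_per_second(counts)
  n_min <- length(v) %/% 60L
  if (n_min == 0L) {
    warning("series shorter than 60 s: empty discrete profile")
    return(new_intensity_profile(scale, character(0), "discrete", 0L,
                                 data.frame(index = integer(0),
                                            cpm = numeric(0),
                                            category = character(0)),
                                 incomplete = TRUE))
  }
  kept <- v[seq_len(n_min * 60L)]
  cpm <- colSums(matrix(kept, nrow = 60L))
  cats <- classify_epoch(cpm, scale)
  detail <- data.frame(index = seq_len(n_min) - 1L, cpm = cpm,
                       category = cats)
  new_intensity_profile(scale, cats, "discrete", n_min, detail)
}

#' Continuous (sliding-window) activity-intensity classification
#'
#' For every second i of a 1-s VM3 count series, forms a one-minute window
#' from the 30 preceding and 30 following seconds (the half-open span
#' `[i - 30, i + 30)`), clipped to the series bounds; a clipped window's sum
#' is rescaled by `60 / window_length` so it stays on the counts-per-minute
#' scale. Each window is classified, giving one overlapping epoch per second
#' — 180 windows for a 3-min series — which makes the profile insensitive to
#' when activity starts relative to acquisition onset.
#'
#' @inheritParams discrete_classification
#' @param window_s window length in seconds: 60 (default, the half-open
#'   span) or 61 (center second plus 30 on each side).
#' @return An `intensity_profile` with one `detail` row per second.
#' @export
continuous_classification <- function(counts, scale = freedson_vm3(),
                                      window_s = 60L) {
  v <- vm3_per_second(counts)
  if (!window_s %in% c(60L, 61L))
    stop_invalid("window_s must be 60 or 61")
  n <- length(v)
  if (n < 1L) stop_invalid("series must have length >= 1")
  csum <- cumsum(c(0, v))
  i <- seq_len(n)
  lo <- pmax(i - 30L, 1L)
  hi <- pmin(i + (window_s - 31L), n)
  len <- hi - lo + 1L
  cpm <- (csum[hi + 1L] - csum[lo]) * 60 / len
  cats <- classify_epoch(cpm, scale)
  detail <- data.frame(index = i - 1L, cpm = cpm, category = cats)
  new_intensity_profile(scale, cats, "continuous", n, detail)
}

#' Load a cut-point scale from JSON
#'
#' Layout: `{"name": ..., "categories": [{"name": "Light", "lower": 0}, ...]}`.
#'
#' @param path JSON file or string.
#' @return A [cutpoint_scale()].
#' @export
cutpoints_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  cutpoint_scale(doc$name, doc$categories)
}

#' Write a cut-point scale to JSON
#'
#' @param scale a [cutpoint_scale()].
#' @param path file to write; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
cutpoints_to_json <- function(scale, path = NULL) {
  js <- jsonlite::toJSON(list(name = scale$name,
                              categories = scale$categories),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
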