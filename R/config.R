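# Tracker configuration and YAML (de)serialization.

#' Tracker configuration
#'
#' All tunable parameters of the matching pipeline. The template/search crop
#' sizes default to the classical Siamese-tracking geometry of 127 px
#' template patches inside 255 px search regions; the five aspect-ratio
#' anchors and the scale candidates realize shape adaptation of the output
#' box by explicit candidate search.
#'
#' @param template_size Side of the square template patch, px (default 127).
#' @param search_size Side of the square search patch, px (default 255);
#'   must exceed `template_size`.
#' @param context_factor Amount `p = context_factor * (w + h)` of context
#'   added around the annotated box before cropping; the crop side is
#'   `sqrt((w + p) * (h + p))` (default 0.5).
#' @param anchor_ratios Exactly five aspect-ratio candidates applied to the
#'   previous box (default `c(1/3, 1/2, 1, 2, 3)`).
#' @param scale_candidates Multiplicative scale candidates (default
#'   `c(0.96, 1, 1.04)`).
#' @param window_weight Weight in `[0, 1)` of the raised-cosine motion prior
#'   blended into the normalized response map (default 0.35).
#' @param distractor_alpha Strength of distractor suppression, >= 0
#'   (default 0.5).
#' @param distractor_peak_fraction Secondary response peaks at least this
#'   fraction of the primary peak are memorized as distractors (default 0.8).
#' @param distractor_memory Maximum number of remembered distractors
#'   (default 5); once full, newly mined ones are evicted first, keeping the
#'   crops mined while the tracker was still reliably on the target.
#' @param confidence_temperature Softmax temperature of the output
#'   confidence, > 0 (default 0.1); applied to min-max normalized scores so
#'   it is scale-free.
#' @param size_damping Blend factor in `(0, 1]` between the previous box size
#'   and the winning candidate's size (default 0.3).
#' @param shape_penalty Multiplicative penalty `exp(-shape_penalty * (|log r|
#'   + |log s|))` applied to the windowed peak score of a non-identity
#'   candidate with ratio `r` and scale `s` (default 0.15), so box-shape
#'   changes only win when the response is genuinely better; prevents
#'   cumulative shape runaway when two look-alike blobs merge.
#' @param feature_stride Pixels per feature cell of the handcrafted
#'   extractor, within a crop patch (default 4).
#' @param extractor Registered feature-extractor id (default `"pix-grad"`).
#' @return Object of class `tracker_config`.
#' @export
tracker_config <- function(template_size = 127L,
                           search_size = 255L,
                           context_factor = 0.5,
                           anchor_ratios = c(1 / 3, 1 / 2, 1, 2, 3),
                           scale_candidates = c(0.96, 1, 1.04),
                           window_weight = 0.35,
                           distractor_alpha = 0.5,
                           distractor_peak_fraction = 0.8,
                           distractor_memory = 5L,
                           confidence_temperature = 0.1,
                           size_damping = 0.3,
                           shape_penalty = 0.15,
                           feature_stride = 4L,
                           extractor = "pix-grad") {
  cfg <- list(
    template_size = as.integer(template_size),
    search_size = as.integer(search_size),
    context_factor = as.numeric(context_factor),
    anchor_ratios = as.numeric(anchor_ratios),
    scale_candidates = as.numeric(scale_candidates),
    window_weight = as.numeric(window_weight),
    distractor_alpha = as.numeric(distractor_alpha),
    distractor_peak_fraction = as.numeric(distractor_peak_fraction),
    distractor_memory = as.integer(distractor_memory),
    confidence_temperature = as.numeric(confidence_temperature),
    size_damping = as.numeric(size_damping),
    shape_penalty = as.numeric(shape_penalty),
    feature_stride = as.integer(feature_stride),
    extractor = as.character(extractor)
  )
  validate_tracker_config(cfg)
  structure(cfg, class = "tracker_config")
}

validate_tracker_config <- function(cfg) {
  if (cfg$template_size >= cfg$search_size) {
    stopf("tracker_config: template_size must be < search_size")
  }
  if (cfg$template_size < 8L) stopf("tracker_config: template_size too small")
  if (length(cfg$anchor_ratios) != 5L) {
    stopf("tracker_config: exactly 5 anchor_ratios are required")
  }
  if (any(cfg$anchor_ratios <= 0) || any(cfg$scale_candidates <= 0)) {
    stopf("tracker_config: anchors and scales must be positive")
  }
  if (cfg$window_weight < 0 || cfg$window_weight >= 1) {
    stopf("tracker_config: window_weight must lie in [0, 1)")
  }
  if (cfg$distractor_alpha < 0) stopf("tracker_config: distractor_alpha must be >= 0")
  if (cfg$distractor_peak_fraction <= 0 || cfg$distractor_peak_fraction >= 1) {
    stopf("tracker_config: distractor_peak_fraction must lie in (0, 1)")
  }
  if (cfg$distractor_memory < 0L) stopf("tracker_config: distractor_memory must be >= 0")
  if (cfg$confidence_temperature <= 0) {
    stopf("tracker_config: confidence_temperature must be > 0")
  }
  if (cfg$size_damping <= 0 || cfg$size_damping > 1) {
    stopf("tracker_config: size_damping must lie in (0, 1]")
  }
  if (cfg$shape_penalty < 0) stopf("tracker_config: shape_penalty must be >= 0")
  if (cfg$feature_stride < 1L) stopf("tracker_config: feature_stride must be >= 1")
  invisible(cfg)
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("<tracker_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]], digits = 6), collapse = " ")))
  }
  invisible(x)
}

#' Write / read a tracker configuration as YAML
#'
#' Every field of [tracker_config()] is overridable from the file; missing
#' fields keep their defaults.
#'
#' @param cfg A [tracker_config()].
#' @param path YAML file path.
#' @export
write_tracker_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_tracker_config
#' @export
read_tracker_config <- function(path) {
  if (!file.exists(path)) stopf("config file does not exist: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(tracker_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stopf("unknown tracker_config field(s) in %s: %s", path,
          paste(unknown, collapse = ", "))
  }
  do.call(tracker_config, vals)
}

#' Benchmark tracker configurations
#'
#' Scaled-down crop geometries used by the package's synthetic benchmarks,
#' where targets are 10-20 px blobs in ~100 px frames: `"small"` (48 px
#' template / 160 px search, feature stride 2) for the standard fixtures and
#' `"tiny"` (24 / 80, stride 2, a single scale candidate since the blobs do
#' not change size) for the multi-thousand-frame endurance runs.
#' The search/template ratio is wider than the full-size default so the
#' response map covers look-alike blobs well before they touch the target,
#' giving distractor mining a clean window.
#' The full-size default geometry remains [tracker_config()].
#'
#' @param size `"small"` or `"tiny"`.
#' @param ... Overrides forwarded to [tracker_config()].
#' @return A [tracker_config()].
#' @export
fixture_tracker_config <- function(size = c("small", "tiny"), ...) {
  size <- match.arg(size)
  base <- switch(size,
    small = list(template_size = 48L, search_size = 160L, feature_stride = 2L),
    tiny = list(template_size = 24L, search_size = 80L, feature_stride = 2L,
                scale_candidates = 1)
  )
  do.call(tracker_config, utils::modifyList(base, list(...)))
}
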