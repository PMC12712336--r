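# Nine-trait myrmecomorphy (ant-mimicry) accuracy index.
#
# Each trait is a ratio of two linear measurements (mm) mapped to [0, 1],
# 0 = no expression of the ant-like trait, 1 = extreme expression.  The
# overall accuracy score is the arithmetic mean of the nine traits.

#' Trait score names
#'
#' The canonical names and order of the nine myrmecomorphy trait scores.
#'
#' @return Character vector of length nine.
#' @export
trait_names <- function() {
  c("thin_legs", "elong_ceph", "elong_abd", "elong_pedicel",
    "constr_ceph_lat", "constr_ceph_dors",
    "constr_abd_lat", "constr_abd_dors",
    "illusion_coloration")
}

# measurement fields required for the non-constriction ratios
.core_fields <- c("femur3_length", "femur3_width",
                  "ceph_width", "ceph_length",
                  "abd_width", "abd_length", "pedicel_length")
# constriction fields: absent values default to "no constriction" (score 0)
.constr_fields <- c("ceph_width_at_constriction",
                    "ceph_height_at_constriction", "ceph_height_max",
                    "abd_width_at_constriction",
                    "abd_height_at_constriction", "abd_height_max")
.flag_fields <- c("illusion_abd_band", "illusion_ceph_band",
                  "illusion_eye_dark")

# Discrete illusion-by-coloration scores for 0..3 expressed traits.  The
# rounded thirds (0.334, 0.667) are used deliberately so printed scores
# reproduce exactly.
.illusion_levels <- c(0, 0.334, 0.667, 1.0)

#' Construct a specimen measurement record
#'
#' Bundles the linear measurements (mm) and the three colour-illusion
#' indicator flags for a single specimen.  Measurement semantics follow
#' the standard labelling of myrmecomorphy biometrics: third-leg femur
#' length/width, cephalothorax width/length, abdomen width/length,
#' pedicel length, widths/heights at the points of constriction and at
#' the widest/highest points, and three booleans for the colour-illusion
#' traits (abdominal light band, cephalothorax light band, darkening
#' around the posterior lateral eyes).
#'
#' A constriction measurement equal to the corresponding widest/highest
#' measurement encodes "no constriction" (score 0); constriction fields
#' may also be left `NA`, which is treated as no constriction.
#'
#' @param specimen_id Specimen identifier.
#' @param femur3_length,femur3_width Leg III femur length and width (mm).
#' @param ceph_width,ceph_length Cephalothorax width and length (mm).
#' @param abd_width,abd_length Abdomen width and length (mm).
#' @param pedicel_length Pedicel length (mm).
#' @param ceph_width_at_constriction Cephalothorax width at the point of
#'   constriction (dorsal view, mm).
#' @param ceph_height_at_constriction,ceph_height_max Cephalothorax height
#'   at the constriction and at the highest point (lateral view, mm).
#' @param abd_width_at_constriction Abdomen width at the constriction
#'   (dorsal view, mm).
#' @param abd_height_at_constriction,abd_height_max Abdomen height at the
#'   constriction and at the highest point (lateral view, mm).
#' @param illusion_abd_band,illusion_ceph_band,illusion_eye_dark Logical
#'   colour-illusion indicators.
#' @param clade_label Optional cohort/clade label.
#' @return A list of class `specimen_measurements`.
#' @export
#' @examples
#' m <- specimen_measurements("sp1", femur3_length = 1, femur3_width = 0.25,
#'   ceph_width = 0.6, ceph_length = 1, abd_width = 0.5, abd_length = 1,
#'   pedicel_length = 0.1)
#' score_traits(m)
specimen_measurements <- function(specimen_id,
                                  femur3_length, femur3_width,
                                  ceph_width, ceph_length,
                                  abd_width, abd_length,
                                  pedicel_length,
                                  ceph_width_at_constriction = NA_real_,
                                  ceph_height_at_constriction = NA_real_,
                                  ceph_height_max = NA_real_,
                                  abd_width_at_constriction = NA_real_,
                                  abd_height_at_constriction = NA_real_,
                                  abd_height_max = NA_real_,
                                  illusion_abd_band = FALSE,
                                  illusion_ceph_band = FALSE,
                                  illusion_eye_dark = FALSE,
                                  clade_label = NA_character_) {
  m <- list(specimen_id = as.character(specimen_id),
            femur3_length = femur3_length, femur3_width = femur3_width,
            ceph_width = ceph_width, ceph_length = ceph_length,
            abd_width = abd_width, abd_length = abd_length,
            pedicel_length = pedicel_length,
            ceph_width_at_constriction = ceph_width_at_constriction,
            ceph_height_at_constriction = ceph_height_at_constriction,
            ceph_height_max = ceph_height_max,
            abd_width_at_constriction = abd_width_at_constriction,
            abd_height_at_constriction = abd_height_at_constriction,
            abd_height_max = abd_height_max,
            illusion_abd_band = isTRUE(as.logical(illusion_abd_band)),
            illusion_ceph_band = isTRUE(as.logical(illusion_ceph_band)),
            illusion_eye_dark = isTRUE(as.logical(illusion_eye_dark)),
            clade_label = as.character(clade_label))
  for (f in c(.core_fields, .constr_fields)) {
    v <- m[[f]]
    # pedicel length may legitimately be 0 (no visible pedicel)
    ok <- if (f == "pedicel_length") v >= 0 else v > 0
    if (!is.na(v) && !ok)
      stop_mm("measurement '%s' must be positive (got %g)", f, v)
  }
  class(m) <- "specimen_measurements"
  m
}

# one clamped ratio score: 1 - num/den, den must be positive
.ratio_score <- function(num, den, field) {
  if (is.na(den) || den <= 0)
    stop_mm("nonpositive or missing denominator '%s'", field)
  min(1, max(0, 1 - num / den))
}

#' Score the nine myrmecomorphy traits of a specimen
#'
#' Computes the nine trait scores from raw measurements:
#' thin legs `1 - femur width / femur length`; elongation of
#' cephalothorax `1 - width/length`; elongation of abdomen
#' `1 - width/length`; elongation of pedicel
#' `pedicel / (ceph length + abd length + pedicel)`; four constriction
#' scores `1 - dimension at constriction / dimension at widest (highest)
#' point` in dorsal (widths) and lateral (heights) view for
#' cephalothorax and abdomen; and the illusion-by-coloration score
#' (0, 0.334, 0.667 or 1 for 0-3 expressed colour traits).  Raw ratios
#' are clamped to \[0, 1\]; missing constriction measurements score 0.
#'
#' @param m A [specimen_measurements()] record (or a list/one-row
#'   data.frame with the same fields).
#' @return Named numeric vector of the nine scores, in [trait_names()]
#'   order, class `trait_scores`.
#' @export
score_traits <- function(m) {
  m <- as.list(m)
  core <- unlist(m[.core_fields])
  if (all(is.na(core))) stop_mm("unscorable specimen: all measurements missing")
  if (anyNA(core))
    stop_mm("unscorable specimen: missing measurement(s): %s",
            paste(.core_fields[is.na(core)], collapse = ", "))

  constr <- function(at, ref, field) {
    a <- m[[at]]; r <- m[[ref]]
    if (is.na(a) || is.na(r)) return(0)  # no-constriction convention
    .ratio_score(a, r, field)
  }
  nflag <- sum(vapply(.flag_fields, function(f)
    isTRUE(as.logical(m[[f]])), logical(1L)))

  s <- c(
    thin_legs       = .ratio_score(m$femur3_width, m$femur3_length,
                                   "femur3_length"),
    elong_ceph      = .ratio_score(m$ceph_width, m$ceph_length, "ceph_length"),
    elong_abd       = .ratio_score(m$abd_width, m$abd_length, "abd_length"),
    elong_pedicel   = {
      tot <- m$ceph_length + m$abd_length + m$pedicel_length
      if (tot <= 0) stop_mm("nonpositive denominator 'total body length'")
      min(1, max(0, m$pedicel_length / tot))
    },
    constr_ceph_lat  = constr("ceph_height_at_constriction",
                              "ceph_height_max", "ceph_height_max"),
    constr_ceph_dors = constr("ceph_width_at_constriction",
                              "ceph_width", "ceph_width"),
    constr_abd_lat   = constr("abd_height_at_constriction",
                              "abd_height_max", "abd_height_max"),
    constr_abd_dors  = constr("abd_width_at_constriction",
                              "abd_width", "abd_width"),
    illusion_coloration = .illusion_levels[nflag + 1L]
  )
  class(s) <- c("trait_scores", "numeric")
  s
}

#' Overall mimicry accuracy
#'
#' The arithmetic mean of the nine trait scores (all traits summed and
#' divided by 9).
#'
#' @param s Trait scores from [score_traits()], or any numeric vector of
#'   the nine named scores.
#' @return Accuracy score in \[0, 1\].
#' @export
overall_accuracy <- function(s) {
  s <- unclass(s)[trait_names()]
  if (anyNA(s))
    stop_mm("incomplete trait-score record: missing %s",
            paste(trait_names()[is.na(s)], collapse = ", "))
  mean(s)
}

# deterministic round-half-up to 2 decimals (base round() is half-even)
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Classify mimicry accuracy
#'
#' Bins an overall accuracy score: `< 0.15` nonmimic; `>= 0.30` accurate;
#' inaccurate mimics are split into low (rounded score 0.15-0.19) and
#' moderate (0.20-0.29) sub-bins.  The low/moderate boundary is applied
#' to the score rounded to two decimals, matching how the bins are
#' conventionally printed.
#'
#' @param x Numeric vector of accuracy scores in \[0, 1\].
#' @return Factor with levels `nonmimic`, `inaccurate_low`,
#'   `inaccurate_moderate`, `accurate`.
#' @export
#' @examples
#' classify_accuracy(c(0.10, 0.18, 0.25, 0.30))
classify_accuracy <- function(x) {
  if (any(is.na(x)) || any(x < 0 | x > 1))
    stop_mm("accuracy scores must lie in [0, 1]")
  lv <- c("nonmimic", "inaccurate_low", "inaccurate_moderate", "accurate")
  out <- ifelse(x < 0.15, "nonmimic",
         ifelse(x >= 0.30, "accurate",
         ifelse(.round2(x) <= 0.19, "inaccurate_low", "inaccurate_moderate")))
  factor(out, levels = lv)
}

#' Score a table of specimens
#'
#' Applies [score_traits()], [overall_accuracy()] and
#' [classify_accuracy()] to every row of a measurement table.
#'
#' @param df Data frame with the [specimen_measurements()] columns (one
#'   row per specimen).
#' @return Data frame: `specimen_id`, `clade_label`, the nine trait
#'   scores, `overall_accuracy`, `category`.
#' @export
score_specimens <- function(df) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    s <- score_traits(df[i, , drop = FALSE])
    acc <- overall_accuracy(s)
    data.frame(specimen_id = as.character(df$specimen_id[i] %||% i),
               clade_label = as.character(
                 if ("clade_label" %in% names(df)) df$clade_label[i] else NA),
               as.list(unclass(s)),
               overall_accuracy = acc,
               category = as.character(classify_accuracy(acc)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort summary statistics
#'
#' Per-trait and overall minimum, maximum, mean and sample (n-1)
#' standard deviation, plus accuracy-category counts and constriction
#' prevalence, for a scored cohort.
#'
#' @param scores Data frame from [score_specimens()].
#' @param clade_label Optional label stored with the summary.
#' @param digits Rounding applied to the summary table (default 2,
#'   matching conventional presentation); use `NULL` for no rounding.
#' @return List of class `cohort_summary` with elements `clade_label`,
#'   `n`, `table` (stat rows per trait + overall), `category_counts`,
#'   `n_constricted_any` (specimens with any of the four constriction
#'   scores > 0), `n_constricted_by_region` (per constriction trait),
#'   and `n_illusion` (specimens with illusion score > 0).
#' @export
cohort_summary <- function(scores, clade_label = NA_character_,
                           digits = 2) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0L) stop_mm("empty cohort")
  if (nrow(scores) == 1L)
    warning("single-record cohort: SD reported as 0", call. = FALSE)
  vars <- c(trait_names(), "overall_accuracy")
  tab <- t(vapply(vars, function(v) {
    x <- scores[[v]]
    c(minimum = min(x), maximum = max(x), mean = mean(x),
      sd = if (length(x) > 1L) sd(x) else 0)
  }, numeric(4L)))
  if (!is.null(digits)) tab <- round(tab, digits)
  cats <- table(factor(scores$category,
                       levels = levels(classify_accuracy(0))))
  constr <- c("constr_ceph_lat", "constr_ceph_dors",
              "constr_abd_lat", "constr_abd_dors")
  structure(list(
    clade_label = clade_label,
    n = nrow(scores),
    table = as.data.frame(tab),
    category_counts = c(cats),
    n_constricted_any = sum(rowSums(scores[constr] > 0) > 0),
    n_constricted_by_region = vapply(scores[constr],
                                     function(x) sum(x > 0), integer(1L)),
    n_illusion = sum(scores$illusion_coloration > 0)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary%s (n = %d)\n",
              if (is.na(x$clade_label)) "" else paste0(": ", x$clade_label),
              x$n))
  print(x$table)
  cat("categories:", paste(names(x$category_counts), x$category_counts,
                           sep = "=", collapse = "  "), "\n")
  cat(sprintf("constricted (any of four traits): %d; illusion expressed: %d\n",
              x$n_constricted_any, x$n_illusion))
  invisible(x)
}

#' Read a specimen measurement table
#'
#' Reads a comma- or tab-separated table whose header uses the
#' [specimen_measurements()] field names.  Illusion flags may be coded
#' 0/1 or true/false.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return Data frame suitable for [score_specimens()].
#' @export
read_measurements <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep,
                   stringsAsFactors = FALSE)
  need <- c("specimen_id", .core_fields)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mm("measurement table lacks column(s): %s",
            paste(miss, collapse = ", "))
  for (f in .flag_fields)
    if (f %in% names(df)) {
      v <- df[[f]]
      df[[f]] <- if (is.character(v)) tolower(v) %in% c("true", "t", "1", "yes")
                 else as.logical(v) %in% TRUE
    } else df[[f]] <- FALSE
  for (f in .constr_fields) if (!f %in% names(df)) df[[f]] <- NA_real_
  df
}
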