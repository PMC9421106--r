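#' Synthetic LMS weight-for-height reference table
#'
#' Builds a smooth, monotone LMS (lambda-mu-sigma) reference for weight given
#' height/length, by sex, in the same tabular format as the WHO 2006 growth
#' standards (columns `sex`, `key`, `L`, `M`, `S`).  The median curve follows
#' a monotone spline through plausible weight-for-height anchor points for
#' children 6-59 months; the skewness (`L`) and coefficient of variation
#' (`S`) vary slowly with height.  This table is synthetic: it is meant to
#' exercise the z-score machinery with a realistic shape, not to reproduce
#' the WHO reference values.  Real reference tables can be supplied through
#' [read_lms_csv()].
#'
#' @param heights numeric vector of tabulated height keys in cm
#'   (default every 1 cm from 45 to 120).
#' @return a tibble with columns `sex` ("M"/"F"), `key` (height, cm),
#'   `L`, `M` (kg), `S`, sorted by sex then key.
#' @export
synthetic_lms_table <- function(heights = seq(45, 120, by = 1)) {
  anchors_h <- c(45, 55, 65, 75, 85, 95, 105, 110, 120)
  anchors_m <- c(2.4, 4.5, 7.4, 9.5, 11.7, 13.8, 16.2, 18.0, 21.5)
  mfun <- stats::splinefun(anchors_h, anchors_m, method = "hyman")
  build_sex <- function(sex, m_scale) {
    tibble(
      sex = sex,
      key = heights,
      L   = -0.35 + 0.0008 * (heights - 45),
      M   = mfun(heights) * m_scale,
      S   = 0.085 + 0.00012 * (heights - 45)
    )
  }
  out <- bind_rows(build_sex("M", 1), build_sex("F", 0.97))
  arrange(out, .data$sex, .data$key)
}

#' Read an LMS reference table from CSV
#'
#' Expects one header row and columns `sex`, `key`, `L`, `M`, `S`; keys must
#' be unique and sorted within sex, `M > 0` and `S > 0`.
#'
#' @param path path to a CSV file.
#' @return a validated tibble in the same layout as [synthetic_lms_table()].
#' @export
read_lms_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  validate_lms(tab)
}

validate_lms <- function(tab) {
  need <- c("sex", "key", "L", "M", "S")
  if (!all(need %in% names(tab))) {
    abort(paste("LMS table must have columns:", paste(need, collapse = ", ")))
  }
  if (any(tab$M <= 0) || any(tab$S <= 0)) abort("LMS table requires M > 0 and S > 0")
  tab <- arrange(as_tibble(tab), .data$sex, .data$key)
  if (any(duplicated(tab[, c("sex", "key")]))) abort("duplicate (sex, key) rows in LMS table")
  tab
}

# Interpolate L, M, S at arbitrary keys for one sex.  Keys outside the
# tabulated range return NA rows (out-of-reference).
lms_interp <- function(reference, sex, key) {
  out <- matrix(NA_real_, nrow = length(key), ncol = 3,
                dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex)) {
    ref <- reference[reference$sex == s, ]
    idx <- which(sex == s)
    if (nrow(ref) == 0) next
    ok <- key[idx] >= min(ref$key) & key[idx] <= max(ref$key) & !is.na(key[idx])
    for (col in c("L", "M", "S")) {
      out[idx[ok], col] <- approx(ref$key, ref[[col]], xout = key[idx][ok])$y
    }
  }
  out
}

# LMS forward transform: z given the measured value and (L, M, S).
lms_z <- function(value, L, M, S) {
  ifelse(abs(L) < 1e-12, log(value / M) / S, ((value / M)^L - 1) / (L * S))
}

# LMS inverse transform: measured value that yields z at (L, M, S).
lms_value <- function(z, L, M, S) {
  ifelse(abs(L) < 1e-12, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Compute weight-for-height z-scores from an LMS reference
#'
#' Applies the LMS transform z = ((w / M)^L - 1) / (L S), with the reference
#' parameters linearly interpolated at each child's height between tabulated
#' keys.  Children whose height falls outside the reference range, or with a
#' missing weight/height/sex, receive `NA` (treated downstream as a missing
#' z-score).  Records that already carry a `whz` value are left untouched.
#'
#' @param children tibble of child records with columns `sex`, `weight_kg`,
#'   `height_cm` and optionally `whz`.
#' @param reference an LMS table as from [synthetic_lms_table()] or
#'   [read_lms_csv()].
#' @return `children` with the `whz` column filled where computable.
#' @export
compute_whz <- function(children, reference) {
  reference <- validate_lms(reference)
  children <- as_tibble(children)
  if (!"whz" %in% names(children)) children$whz <- NA_real_
  todo <- is.na(children$whz)
  if (!any(todo)) return(children)
  par <- lms_interp(reference, children$sex[todo], children$height_cm[todo])
  z <- lms_z(children$weight_kg[todo], par[, "L"], par[, "M"], par[, "S"])
  children$whz[todo] <- z
  children
}
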