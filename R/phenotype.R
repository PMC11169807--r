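#' Compatibility index
#'
#' CI = number of seeds set per self-pollinated flower.
#'
#' @param n_seeds seed count(s).
#' @param n_flowers pollinated flower count(s), > 0.
#' @return Numeric ratio(s); use [round()] to the printed precision for
#'   reporting.
#' @export
compute_ci <- function(n_seeds, n_flowers) {
  if (any(n_flowers <= 0)) stop("n_flowers must be positive")
  if (any(n_seeds < 0)) stop("n_seeds must be non-negative")
  n_seeds / n_flowers
}

#' Classify a compatibility index
#'
#' Self-incompatible (SI) when CI < 1, moderately self-compatible (MSC)
#' when 1 <= CI <= 4, self-compatible (SC) when CI > 4.
#'
#' @param ci compatibility index value(s), >= 0.
#' @return Character vector of `"SI"`, `"MSC"`, `"SC"`.
#' @export
classify_ci <- function(ci) {
  if (any(ci < 0)) stop("ci must be non-negative")
  ifelse(ci < 1, "SI", ifelse(ci <= 4, "MSC", "SC"))
}

#' Classify a pollen-tube count
#'
#' SI when fewer than 10 pollen tubes penetrate the stigma, MSC for
#' 10-25, SC above 25.
#'
#' @param npt pollen-tube count(s), >= 0.
#' @return Character vector of `"SI"`, `"MSC"`, `"SC"`.
#' @export
classify_npt <- function(npt) {
  if (any(npt < 0)) stop("npt must be non-negative")
  ifelse(npt < 10, "SI", ifelse(npt <= 25, "MSC", "SC"))
}

#' Tally compatibility classes
#'
#' @param records data frame with a `ci_class` column (or a character
#'   vector of classes).
#' @return Named integer vector with counts for `SC`, `MSC`, `SI`.
#' @export
ci_summary <- function(records) {
  cls <- if (is.data.frame(records)) records$ci_class else records
  out <- c(SC = 0L, MSC = 0L, SI = 0L)
  if (length(cls)) {
    tab <- table(factor(cls, levels = names(out)))
    out[] <- as.integer(tab)
  }
  out
}

#' Read pollination records and classify them
#'
#' @param path TSV with columns `id`, `flowers`, `seeds`.
#' @return Data frame with added `ci` and `ci_class` columns.
#' @export
read_pollination_records <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "flowers", "seeds")
  if (!all(need %in% names(df))) {
    stop("pollination file must have columns: ", paste(need, collapse = ", "))
  }
  df$ci <- compute_ci(df$seeds, df$flowers)
  df$ci_class <- classify_ci(df$ci)
  df
}
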