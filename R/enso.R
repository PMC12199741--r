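# Monthly ENSO phase series: synthetic generation and CSV IO.

ENSO_PHASES <- c("El Nino", "La Nina", "Neutral")

#' Generate a synthetic monthly ENSO phase series
#'
#' Draws an independent phase label per month with the given probabilities.
#'
#' @param start,end first and last month (`"YYYY-MM"` or dates).
#' @param probs probabilities for (El Nino, La Nina, Neutral); must sum
#'   to 1.
#' @param seed RNG seed.
#' @return an `enso_series`: data.frame with `month` (`"YYYY-MM"`) and
#'   `phase`.
#' @export
make_enso <- function(start, end, probs = c(0.25, 0.25, 0.5), seed = 1L) {
  abort_if(abs(sum(probs) - 1) > 1e-9 || any(probs < 0),
           "phase probabilities must be non-negative and sum to 1")
  s <- as.Date(paste0(substr(start, 1, 7), "-01"))
  e <- as.Date(paste0(substr(end, 1, 7), "-01"))
  abort_if(e < s, "end month before start month")
  months <- format(seq(s, e, by = "month"), "%Y-%m")
  phase <- with_seed(seed, function()
    sample(ENSO_PHASES, length(months), replace = TRUE, prob = probs))
  structure(data.frame(month = months, phase = phase),
            class = c("enso_series", "data.frame"))
}

#' Read / write a monthly ENSO phase CSV
#'
#' CSV columns: `year`, `month` (1-12), `phase` (one of `El Nino`,
#' `La Nina`, `Neutral`).
#'
#' @param path file path.
#' @param enso an `enso_series` (writer).
#' @return an `enso_series` (reader) / `path` (writer).
#' @export
read_enso_csv <- function(path) {
  df <- utils::read.csv(path)
  abort_if(!all(c("year", "month", "phase") %in% names(df)),
           "ENSO CSV needs year, month, phase columns")
  bad <- !df$phase %in% ENSO_PHASES
  abort_if(any(bad), "unknown ENSO phase label(s): %s",
           paste(unique(df$phase[bad]), collapse = ", "))
  structure(data.frame(month = sprintf("%04d-%02d", df$year, df$month),
                       phase = df$phase),
            class = c("enso_series", "data.frame"))
}

#' @rdname read_enso_csv
#' @export
write_enso_csv <- function(enso, path) {
  utils::write.csv(data.frame(
    year = as.integer(substr(enso$month, 1, 4)),
    month = as.integer(substr(enso$month, 6, 7)),
    phase = enso$phase), path, row.names = FALSE)
  invisible(path)
}
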