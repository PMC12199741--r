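# DNA barcode matching: global pairwise alignment, percent identity,
# ranking against a reference, and the multi-marker confirmation rule.

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Optimal global alignment under linear gap scores (defaults: match +1,
#' mismatch -1, gap -2). Ties in the dynamic program break
#' deterministically: diagonal is preferred, then the gap in the second
#' sequence ("up"). Input is case-normalised to upper case.
#'
#' @param a,b unaligned nucleotide strings.
#' @param match,mismatch,gap scoring parameters.
#' @return list with aligned strings `a`, `b` (same length, `-` gaps) and
#'   the optimal `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  abort_if(nchar(a) == 0 || nchar(b) == 0, "sequences must be non-empty")
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  P <- matrix(0L, n + 1, m + 1)   # 1 diag, 2 up (gap in b), 3 left
  S[, 1] <- gap * (0:n)
  S[1, ] <- gap * (0:m)
  P[2:(n + 1), 1] <- 2L
  P[1, 2:(m + 1)] <- 3L
  for (i in 1:n) {
    sub <- ifelse(A[i] == B, match, mismatch)
    row_prev <- S[i, ]
    row_cur <- S[i + 1, ]
    for (j in 1:m) {
      d <- row_prev[j] + sub[j]
      u <- row_prev[j + 1] + gap
      l <- row_cur[j] + gap
      # tie order: diagonal, then up
      if (d >= u && d >= l) { row_cur[j + 1] <- d; P[i + 1, j + 1] <- 1L }
      else if (u >= l) { row_cur[j + 1] <- u; P[i + 1, j + 1] <- 2L }
      else { row_cur[j + 1] <- l; P[i + 1, j + 1] <- 3L }
    }
    S[i + 1, ] <- row_cur
  }
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    mv <- P[i, j]
    if (mv == 1L) {
      ra <- c(A[i - 1], ra); rb <- c(B[j - 1], rb); i <- i - 1; j <- j - 1
    } else if (mv == 2L) {
      ra <- c(A[i - 1], ra); rb <- c("-", rb); i <- i - 1
    } else {
      ra <- c("-", ra); rb <- c(B[j - 1], rb); j <- j - 1
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = S[n + 1, m + 1])
}

#' Percent identity of an aligned pair
#'
#' After stripping terminal-gap columns (leading/trailing gap runs in
#' either row), identity is 100 x matching columns / columns where both
#' rows are non-gap. Internal indels therefore shrink the denominator but
#' ragged amplicon ends do not penalise. Case-insensitive.
#'
#' @param a,b aligned strings of equal length (`-` gaps).
#' @return percent identity in `[0, 100]` (exact; round with
#'   [round_half_up()] for reporting).
#' @export
percent_identity <- function(a, b) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  abort_if(length(A) != length(B), "aligned lengths differ")
  gapA <- A == "-"; gapB <- B == "-"
  # terminal-gap columns: inside the leading or trailing gap run of a row
  run_head <- function(g) { w <- which(!g); if (!length(w)) length(g) else w[1] - 1 }
  lead <- max(run_head(gapA), run_head(gapB))
  trail <- max(run_head(rev(gapA)), run_head(rev(gapB)))
  keep <- seq_along(A) > lead & seq_along(A) <= length(A) - trail
  A <- A[keep]; B <- B[keep]
  comp <- A != "-" & B != "-"
  abort_if(!any(comp), "no comparable (gap-free) columns")
  100 * sum(A[comp] == B[comp]) / sum(comp)
}

#' Rank candidate sequences against a reference by percent identity
#'
#' Every candidate is scored against the reference and the report is sorted
#' by descending identity, ties broken by candidate id order. Pre-aligned
#' input (all sequences the same length, from one multiple alignment) is
#' compared column-wise; unaligned input is pairwise-aligned with
#' [align_pair()] first.
#'
#' @param candidates named character vector of sequences.
#' @param reference reference sequence (string); when `aligned = TRUE` it
#'   must come from the same alignment.
#' @param aligned are the inputs rows of one multiple alignment?
#' @return an `identity_report`: data.frame with `id`, `identity` (exact
#'   percent), `identity_reported` (half-up, one decimal), and
#'   `columns_compared`.
#' @export
rank_against_reference <- function(candidates, reference, aligned = FALSE) {
  if (length(candidates) == 0) {
    return(structure(data.frame(id = character(0), identity = numeric(0),
                                identity_reported = numeric(0),
                                columns_compared = integer(0)),
                     class = c("identity_report", "data.frame")))
  }
  ids <- names(candidates)
  if (is.null(ids)) ids <- paste0("seq", seq_along(candidates))
  rows <- lapply(seq_along(candidates), function(k) {
    if (aligned) {
      pa <- list(a = candidates[[k]], b = reference)
    } else {
      al <- align_pair(candidates[[k]], reference)
      pa <- list(a = al$a, b = al$b)
    }
    idpct <- percent_identity(pa$a, pa$b)
    A <- strsplit(toupper(pa$a), "")[[1]]; B <- strsplit(toupper(pa$b), "")[[1]]
    data.frame(id = ids[k], identity = idpct,
               identity_reported = round_half_up(idpct, 1),
               columns_compared = sum(A != "-" & B != "-"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$identity, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("identity_report", "data.frame"))
}

#' Multi-marker confirmation rule
#'
#' A candidate population is `confirmed` as the reference organism iff all
#' three corroborating barcodes (rbcL, COI, SSU) exceed 99% identity AND an
#' eDNA detection supports it; `provisional` if the barcodes pass without
#' an eDNA detection; `rejected` otherwise.
#'
#' @param identities named numeric vector of percent identities containing
#'   `rbcL`, `COI` and `SSU`.
#' @param edna_detected was the region's eDNA screen positive?
#' @return `"confirmed"`, `"provisional"` or `"rejected"`.
#' @export
confirm_candidate <- function(identities, edna_detected) {
  need <- c("rbcL", "COI", "SSU")
  miss <- setdiff(need, names(identities))
  abort_if(length(miss) > 0, "missing marker identity: %s",
           paste(miss, collapse = ", "))
  pass <- all(identities[need] > 99)
  if (pass && isTRUE(edna_detected)) "confirmed"
  else if (pass) "provisional"
  else "rejected"
}

#' Generate a family of diverged marker sequences
#'
#' Mutates the reference independently at each site with probability `d`
#' (to a uniformly-chosen different base), so the expected pairwise
#' identity to the reference is `100 * (1 - d)` percent.
#'
#' @param reference reference nucleotide string.
#' @param n number of sequences.
#' @param d per-site divergence probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return named character vector of sequences (`var1`...`varn`).
#' @export
make_markers <- function(reference, n, d, seed = 1L) {
  abort_if(d < 0 || d >= 1, "d must be in [0, 1)")
  ref <- strsplit(toupper(reference), "")[[1]]
  bases <- c("A", "C", "G", "T")
  out <- with_seed(seed, function() {
    vapply(seq_len(n), function(k) {
      hit <- stats::runif(length(ref)) < d
      seq <- ref
      if (any(hit)) {
        seq[hit] <- vapply(seq[hit], function(b)
          sample(setdiff(bases, b), 1), "")
      }
      paste(seq, collapse = "")
    }, "")
  })
  stats::setNames(out, paste0("var", seq_len(n)))
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors; `-` gap characters (pre-aligned FASTA) pass through; output is
#' wrapped at 60 columns.
#'
#' @param path file path.
#' @param seqs named character vector (writer).
#' @return named character vector (reader) / `path` (writer).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 60)
  invisible(path)
}
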