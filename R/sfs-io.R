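defaultMask <- function(n, folded) {
  mask <- rep(FALSE, n + 1L)
  mask[c(1L, n + 1L)] <- TRUE
  if (folded && n >= 2L) mask[seq.int(floor(n / 2) + 2L, n + 1L)] <- TRUE
  mask
}

#' Construct a site frequency spectrum
#'
#' @param counts numeric vector of length \code{n + 1} of variant counts by
#'   allele-count class (entry 1 is the unobservable 0-class).
#' @param folded logical; is the spectrum folded (minor-allele counts)?
#' @param mask optional logical mask; defaults to masking entries 0 and n,
#'   plus everything above n/2 when folded.
#'
#' @return an \linkS4class{SFS}.
#' @examples
#' sfs(c(0, 6, 3, 2, 0))                  # unfolded, n = 4
#' sfs(c(0, 8, 3, 0, 0), folded = TRUE)
#' @export
sfs <- function(counts, folded = FALSE, mask = NULL) {
  n <- length(counts) - 1L
  if (is.null(mask)) mask <- defaultMask(n, folded)
  counts[mask] <- counts[mask] * 0  # keep masked entries but zero any NA
  counts[mask][!is.finite(counts[mask])] <- 0
  new("SFS", counts = as.numeric(counts), n = as.integer(n),
      folded = isTRUE(folded), mask = as.logical(mask))
}

#' Read a dadi-style SFS text file
#'
#' The dialect is a single spectrum: a header line \code{"<n+1> folded"} or
#' \code{"<n+1> unfolded"}, one line of \code{n + 1} counts, and one line of
#' \code{n + 1} 0/1 mask flags (1 = masked).
#'
#' @param path file path.
#' @param strict if \code{TRUE}, require all unmasked counts to be integers
#'   (observed spectra); expected spectra are real-valued.
#' @return an \linkS4class{SFS}.
#' @seealso [writeSFS()]
#' @export
readSFS <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L)
    stop("SFS file must have header, data and mask lines: ", path)
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L || is.na(suppressWarnings(as.integer(hdr[1L]))) ||
      !(hdr[2L] %in% c("folded", "unfolded")))
    stop("malformed SFS header (expected \"<n+1> folded|unfolded\"): ",
         lines[1L])
  len <- as.integer(hdr[1L])
  folded <- hdr[2L] == "folded"
  counts <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1L]]))
  if (length(counts) != len || any(is.na(counts)))
    stop(sprintf("data line must hold %d numeric entries (line 2)", len))
  maskRaw <- suppressWarnings(as.integer(strsplit(trimws(lines[3L]), "\\s+")[[1L]]))
  if (length(maskRaw) != len || any(is.na(maskRaw)) || any(!maskRaw %in% 0:1))
    stop(sprintf("mask line must hold %d 0/1 entries (line 3)", len))
  mask <- maskRaw == 1L
  if (any(counts[!mask] < 0))
    stop("negative unmasked counts in data line (line 2)")
  if (strict && any(counts[!mask] %% 1 != 0))
    stop("strict = TRUE requires integer unmasked counts (line 2)")
  sfs(counts, folded = folded, mask = mask)
}

#' Write a dadi-style SFS text file
#'
#' @param x an \linkS4class{SFS}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso [readSFS()]
#' @export
writeSFS <- function(x, path) {
  stopifnot(is(x, "SFS"))
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                           collapse = " ")
  writeLines(c(paste(x@n + 1L, if (x@folded) "folded" else "unfolded"),
               fmt(x@counts), fmt(as.integer(x@mask))), path)
  invisible(path)
}

#' Fold an unfolded SFS
#'
#' Tabulates minor-allele counts: \code{folded[i] = counts[i] + counts[n-i]}
#' for \eqn{i < n/2} and \code{folded[n/2] = counts[n/2]} when \eqn{n} is
#' even (the central class is stored once).  Total unmasked count mass is
#' conserved.
#'
#' @param x an unfolded \linkS4class{SFS}.
#' @return a folded \linkS4class{SFS}.
#' @examples
#' foldSFS(sfs(c(0, 3, 2, 1, 0)))  # counts become c(0, 4, 2, 0, 0)
#' @export
foldSFS <- function(x) {
  stopifnot(is(x, "SFS"))
  if (x@folded) stop("SFS is already folded")
  n <- x@n
  half <- floor(n / 2)
  out <- numeric(n + 1L)
  for (i in seq_len(half)) {
    j <- n - i
    out[i + 1L] <- x@counts[i + 1L] + if (j != i) x@counts[j + 1L] else 0
  }
  mask <- defaultMask(n, TRUE)
  # a class is masked in the folded spectrum if either contributor was masked
  for (i in seq_len(half)) {
    j <- n - i
    if (x@mask[i + 1L] || x@mask[j + 1L]) {
      mask[i + 1L] <- TRUE
      out[i + 1L] <- 0
    }
  }
  sfs(out, folded = TRUE, mask = mask)
}

#' Synonymous/nonsynonymous site counts
#'
#' @param LS number of synonymous sites.
#' @param ratio nonsynonymous/synonymous length ratio (default 2.31).
#' @param LNS nonsynonymous length; derived as \code{ratio * LS} if missing.
#' @return a \linkS4class{SiteCounts}.
#' @export
siteCounts <- function(LS, ratio = 2.31, LNS = ratio * LS) {
  new("SiteCounts", LS = LS, LNS = LNS, ratio = ratio)
}
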