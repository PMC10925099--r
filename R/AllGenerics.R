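#' @rdname SFS-class
#' @param object,x an object.
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname SFS-class
#' @export
setGeneric("sampleSize", function(x) standardGeneric("sampleSize"))

#' @rdname SFS-class
#' @export
setGeneric("isFolded", function(x) standardGeneric("isFolded"))

#' @rdname SFS-class
#' @export
setGeneric("sfsMask", function(x) standardGeneric("sfsMask"))

#' @rdname DiscreteDFE-class
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname DominanceMap-class
#' @export
setGeneric("hValues", function(x) standardGeneric("hValues"))

#' @rdname SimResult-class
#' @export
setGeneric("simStats", function(x) standardGeneric("simStats"))

#' @rdname SFS-class
#' @export
setMethod("counts", "SFS", function(x) x@counts)

#' @rdname SFS-class
#' @export
setMethod("sampleSize", "SFS", function(x) x@n)

#' @rdname SFS-class
#' @export
setMethod("isFolded", "SFS", function(x) x@folded)

#' @rdname SFS-class
#' @export
setMethod("sfsMask", "SFS", function(x) x@mask)

#' @rdname DiscreteDFE-class
#' @export
setMethod("proportions", "DiscreteDFE", function(x) x@proportions)

#' @rdname DominanceMap-class
#' @export
setMethod("hValues", "DominanceMap", function(x) x@h)

#' @rdname SimResult-class
#' @export
setMethod("simStats", "SimResult", function(x) x@stats)

setMethod("show", "SFS", function(object) {
  cat(sprintf("%s SFS: n = %d chromosomes, %d unmasked classes, %.6g segregating sites\n",
              if (object@folded) "folded" else "unfolded", object@n,
              sum(!object@mask), sum(object@counts[!object@mask])))
  i <- which(!object@mask) - 1L
  k <- min(length(i), 8L)
  cat("  x[", paste(i[seq_len(k)], collapse = ","),
      if (length(i) > k) ",...]" else "]", " = ",
      paste(signif(object@counts[i[seq_len(k)] + 1L], 5), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "EpochModel", function(object) {
  cat("EpochModel with", nrow(object@epochs), "epoch(s) after the ancestral equilibrium:\n")
  print(object@epochs, row.names = FALSE)
})

setMethod("show", "GammaDFE", function(object) {
  cat(sprintf("GammaDFE: shape = %.4g, scale = %.4g (s units), E[s] = %.4g\n",
              object@shape, object@scale, object@shape * object@scale))
})

setMethod("show", "DiscreteDFE", function(object) {
  cat("DiscreteDFE proportions:\n")
  print(setNames(round(object@proportions, 4),
                 c("neutral", "nearly", "weak", "moderate", "strong")))
})

setMethod("show", "DominanceMap", function(object) {
  cat("DominanceMap h:\n")
  print(setNames(object@h, c("neutral", "nearly", "weak", "moderate", "strong")))
})

setMethod("show", "HSModel", function(object) {
  cat(sprintf("HSModel: LL = %.3f, AIC = %.3f\n", object@LL, object@AIC))
  cat("  h:", paste(object@hmap@h, collapse = " "), "\n")
  cat("  p:", paste(round(object@dfe@proportions, 3), collapse = " "), "\n")
})

setMethod("show", "SFSCache", function(object) {
  cat(sprintf("SFSCache: %d spectra, s in [%.3g, %.3g], h = %.3g, n = %d, Nanc = %.6g\n",
              length(object@s), min(object@s), max(object@s), object@h,
              object@n, object@Nanc))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: LL = %.4f, k = %d, AIC = %.4f, converged = %s (%d starts)\n",
              object@LL, object@k, object@AIC, object@converged, object@nStarts))
  str(object@params, give.attr = FALSE)
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: lambda = %g, projection factor = %g, %d rows\n",
              object@lambda, object@factor, nrow(object@stats)))
  print(utils::head(object@stats, 10), row.names = FALSE)
})

setMethod("show", "TwoPopDemography", function(object) {
  cat("TwoPopDemography parameters (diploids; generations before present):\n")
  print(object@params)
})

#' @rdname HSModel-class
#' @export
setMethod("hValues", "HSModel", function(x) x@hmap@h)

#' @rdname HSModel-class
#' @export
setMethod("proportions", "HSModel", function(x) x@dfe@proportions)
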