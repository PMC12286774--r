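#' @include AllClasses.R
NULL

#' Accessors for pipeline objects
#'
#' `contigIds()`, `contigLengths()`, `contigCoverage()`, `contigLibrary()`
#' and `contigSequences()` read the components of a [ContigSet-class];
#' `tpmMatrix()` and `libraryIds()` read an [AbundanceMatrix-class];
#' `passes()` and `failReasons()` read an [RdrpCandidate-class];
#' `clusterMembers()`, `clusterStatus()`, `qcFlags()` and `anchorId()`
#' read a [SegmentCluster-class].
#'
#' @param x The object.
#' @return The respective component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))
#' @rdname accessors
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))
#' @rdname accessors
#' @export
setGeneric("contigCoverage", function(x) standardGeneric("contigCoverage"))
#' @rdname accessors
#' @export
setGeneric("contigLibrary", function(x) standardGeneric("contigLibrary"))
#' @rdname accessors
#' @export
setGeneric("contigSequences", function(x) standardGeneric("contigSequences"))
#' @rdname accessors
#' @export
setGeneric("tpmMatrix", function(x) standardGeneric("tpmMatrix"))
#' @rdname accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))
#' @rdname accessors
#' @export
setGeneric("passes", function(x) standardGeneric("passes"))
#' @rdname accessors
#' @export
setGeneric("failReasons", function(x) standardGeneric("failReasons"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("clusterStatus", function(x) standardGeneric("clusterStatus"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("anchorId", function(x) standardGeneric("anchorId"))

#' @rdname accessors
#' @export
setMethod("contigIds", "ContigSet", function(x) names(x@sequences))

#' @rdname accessors
#' @export
setMethod("contigIds", "AbundanceMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("contigLengths", "ContigSet", function(x) {
  stats::setNames(width(x@sequences), names(x@sequences))
})

#' @rdname accessors
#' @export
setMethod("contigCoverage", "ContigSet", function(x) {
  stats::setNames(x@coverage, names(x@sequences))
})

#' @rdname accessors
#' @export
setMethod("contigLibrary", "ContigSet", function(x) {
  stats::setNames(x@library, names(x@sequences))
})

#' @rdname accessors
#' @export
setMethod("contigSequences", "ContigSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setMethod("tpmMatrix", "AbundanceMatrix", function(x) assay(x, "tpm"))

#' @rdname accessors
#' @export
setMethod("libraryIds", "AbundanceMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("passes", "RdrpCandidate",
          function(x) length(x@failReasons) == 0L)

#' @rdname accessors
#' @export
setMethod("failReasons", "RdrpCandidate", function(x) x@failReasons)

#' @rdname accessors
#' @export
setMethod("clusterMembers", "SegmentCluster", function(x) x@members)

#' @rdname accessors
#' @export
setMethod("clusterStatus", "SegmentCluster", function(x) x@status)

#' @rdname accessors
#' @export
setMethod("qcFlags", "SegmentCluster", function(x) x@qcFlags)

#' @rdname accessors
#' @export
setMethod("anchorId", "SegmentCluster", function(x) x@anchorId)

#' Subset a ContigSet
#'
#' @param x A [ContigSet-class].
#' @param i Index (contig ids, logical, or integer).
#' @param j,...,drop Ignored.
#' @return A [ContigSet-class] restricted to `i`.
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("ContigSet",
      sequences = x@sequences[i],
      library   = x@library[i],
      coverage  = x@coverage[i])
})

#' @describeIn ContigSet-class Number of contigs.
#' @param x A `ContigSet`.
#' @export
setMethod("length", "ContigSet", function(x) length(x@sequences))

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet with", length(object), "contigs from",
      length(unique(object@library)), "library(ies)\n")
  if (length(object)) {
    cat("  length range:", min(width(object@sequences)), "-",
        max(width(object@sequences)), "nt;",
        sum(is.na(object@coverage)), "contig(s) without coverage\n")
  }
})

setMethod("show", "RdrpCandidate", function(object) {
  cat("RdrpCandidate", object@contigId,
      sprintf("(%d nt, coverage %s)", object@lengthNt,
              ifelse(is.na(object@coverage), "NA",
                     format(object@coverage))), "\n")
  if (passes(object)) cat("  passes all anchor screens\n")
  else cat("  fails:", paste(object@failReasons, collapse = ", "), "\n")
})

setMethod("show", "SegmentCluster", function(object) {
  cat("SegmentCluster", object@clusterId, "--", object@status, "\n")
  cat("  anchor:", object@anchorId,
      sprintf("(prevalence %d libraries)", object@prevalence), "\n")
  cat("  members:", nrow(object@members),
      sprintf("(%d RdRP)", length(object@rdrpIds)))
  if (length(object@qcFlags))
    cat("; flags:", paste(object@qcFlags, collapse = ", "))
  if (!is.na(object@terminalSupport))
    cat("; termini:", object@terminalSupport)
  cat("\n")
})
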