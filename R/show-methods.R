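#' @include AllClasses.R
NULL

setMethod("show", "StockholmAlignment", function(object) {
  cat(sprintf("StockholmAlignment: %d rows x %d columns; %d #=GC annotation(s)\n",
              length(object@rows), alignmentWidth(object), length(object@gc)))
})

setMethod("show", "ProfileModel", function(object) {
  cat(sprintf("ProfileModel '%s': %d match columns (seed MSA columns %d..%d)\n",
              object@sourceNode, nrow(object@scores),
              min(object@columnMap), max(object@columnMap)))
})

setMethod("show", "HitTable", function(object) {
  cat(sprintf("HitTable: %d hit(s), db %g residues\n",
              nrow(object@hits), object@dbSize))
  if (nrow(object@hits))
    print(utils::head(object@hits[, c("query", "target", "bit_score", "evalue")], 5L))
})

setMethod("show", "Cutoffs", function(object) {
  cat(sprintf("Cutoffs: TC=%.2f NC=%.2f GA=%.2f (method: %s)\n",
              object@tc, object@nc, object@ga, object@method))
  if (nzchar(object@diagnostics))
    cat("  diagnostics:", object@diagnostics, "\n")
})

setMethod("show", "HierarchyNode", function(object) {
  describe <- function(node, indent) {
    cat(sprintf("%s%s '%s': %d member(s)%s%s\n",
                strrep("  ", indent), node@level, node@name,
                length(node@members),
                if (!is.null(node@cutoffs))
                  sprintf(", GA=%.1f", node@cutoffs@ga) else "",
                if (nrow(node@residueSpecs))
                  sprintf(", %d residue spec(s)", nrow(node@residueSpecs)) else ""))
    for (ch in node@children) describe(ch, indent + 1L)
  }
  describe(object, 0L)
})

setMethod("show", "AnnotationResult", function(object) {
  cat(sprintf("AnnotationResult '%s': %s%s (evidence: %s)\n", object@query,
              object@assignedLevel,
              if (!is.na(object@assignedNode))
                paste0(" -> ", object@assignedNode) else "",
              object@evidence))
})

setMethod("show", "SimilarityNetwork", function(object) {
  cat(sprintf("SimilarityNetwork (%s): %d node(s), %d edge(s)\n",
              object@kind, nrow(object@nodes), nrow(object@edges)))
})
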