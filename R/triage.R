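#' Read a candidate-gene table
#'
#' Tab- or comma-separated with a header. Required columns: `symbol`,
#' `chr`, `start_mb`, `end_mb`, `coding_variant`, `cis_eqtl`, `correlated`,
#' `prior_phenotype`; flags may be 0/1 or TRUE/FALSE.
#'
#' @param file path or connection.
#' @return a `data.frame` of gene records.
#' @export
read_gene_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  if (!length(lines)) stop("empty file: header required")
  sep <- detect_sep(lines[1])
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("symbol", "chr", "start_mb", "end_mb", "coding_variant",
            "cis_eqtl", "correlated", "prior_phenotype")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (f in c("coding_variant", "cis_eqtl", "correlated", "prior_phenotype"))
    tab[[f]] <- as.logical(tab[[f]])
  if (any(tab$start_mb > tab$end_mb)) stop("gene with start_mb > end_mb")
  tab$chr <- as.character(tab$chr)
  tab
}

#' Genes within a QTL support interval
#'
#' Returns the genes on the stated chromosome whose span overlaps the
#' interval at all (closed endpoints: a gene straddling a boundary is
#' included), optionally restricted to genes carrying a coding variant
#' (nsSNP or InDel).
#'
#' @param genes gene-record `data.frame` (see [read_gene_table()]).
#' @param chromosome chromosome label.
#' @param interval numeric `c(lower, upper)` in Mb, lower <= upper.
#' @param require_coding_variant keep only `coding_variant == TRUE` genes.
#' @return the selected rows of `genes`.
#' @export
interval_candidates <- function(genes, chromosome, interval,
                                require_coding_variant = FALSE) {
  if (length(interval) != 2 || anyNA(interval) || interval[1] > interval[2])
    stop("malformed interval: need c(lower, upper) with lower <= upper")
  if (!nrow(genes)) return(genes)
  keep <- genes$chr == as.character(chromosome) &
    genes$start_mb <= interval[2] & genes$end_mb >= interval[1]
  if (require_coding_variant) keep <- keep & genes$coding_variant
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate genes by evidence-list intersection
#'
#' Each gene carries three independent evidence flags: a cis-eQTL for its
#' own transcript, correlation of its expression with the mapped trait, and
#' a prior phenotype association (e.g. knockout effects on brain, behavior,
#' or cranio-facial morphology). The evidence tier is the number of flags
#' set; genes in all three lists form the top tier, and the union is every
#' gene appearing in at least one list.
#'
#' @param genes gene-record `data.frame` with the three evidence flags.
#' @return a list of class `evidence_rank`: `tiers` (list of symbol
#'   vectors for tiers 0-3), `tier_counts`, `union` (symbols with >= 1
#'   flag), `top` (symbols with all three flags).
#' @export
evidence_rank <- function(genes) {
  flags <- c("cis_eqtl", "correlated", "prior_phenotype")
  miss <- setdiff(flags, names(genes))
  if (length(miss))
    stop("missing evidence flag column(s): ", paste(miss, collapse = ", "))
  tier <- if (nrow(genes))
    rowSums(sapply(flags, function(f) as.logical(genes[[f]]))) else integer(0)
  tiers <- lapply(0:3, function(k) sort(unique(genes$symbol[tier == k])))
  names(tiers) <- paste0("tier", 0:3)
  structure(list(tiers = tiers,
                 tier_counts = vapply(tiers, length, integer(1)),
                 union = sort(unique(genes$symbol[tier >= 1])),
                 top = tiers$tier3),
            class = "evidence_rank")
}

#' @export
print.evidence_rank <- function(x, ...) {
  cat("evidence tiers (number of lists a gene appears in):\n")
  for (k in 3:0)
    cat(sprintf("  tier %d: %d gene(s)%s\n", k, x$tier_counts[[k + 1]],
                if (k == 3 && length(x$top))
                  paste0(" [", paste(x$top, collapse = ", "), "]") else ""))
  cat(sprintf("  union (>= 1 list): %d gene(s)\n", length(x$union)))
  invisible(x)
}
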