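#' Paths to packaged example data
#'
#' The package ships two curated candidate-gene tables encoding the
#' published evidence lists for the call-frequency QTL on Chr 2
#' (`chr2_candidates.tsv`) and the call-amplitude QTL on Chr 8
#' (`chr8_candidates.tsv`): gene symbols and their cis-eQTL /
#' trait-correlation / prior-phenotype flags are as published, while the
#' Mb coordinates are approximate placements within each QTL interval.
#'
#' @param file file name; omit to list available files.
#' @return full path to the file (or the available file names).
#' @examples
#' usv_example()
#' genes <- read_gene_table(usv_example("chr8_candidates.tsv"))
#' @export
usv_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "usvqtl")))
  path <- system.file("extdata", file, package = "usvqtl")
  if (path == "") stop("no packaged file named ", file)
  path
}
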