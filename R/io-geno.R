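#' Read a GeneNetwork-style .geno genotype file
#'
#' Parses the tabular `.geno` dialect: optional `@`-prefixed metadata lines
#' declaring the parental, heterozygous, and unknown allele symbols (e.g.
#' `@mat:B`, `@pat:D`, `@het:H`, `@unk:U`; a space separator is also
#' accepted), comment lines starting with `#`, a column header
#' `Chr  Locus  cM  Mb  <strain...>`, and one data row per marker. Allele
#' tokens are mapped through the declared symbols onto the internal codes
#' `B` (maternal), `D` (paternal), `H` (heterozygous), `U` (unknown).
#'
#' @param file path to a `.geno` file, or a connection.
#' @return a `geno_matrix` (see [simulate_ri_genotypes()] for structure).
#' @seealso [write_geno()]
#' @export
read_geno <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  meta_i <- keep & grepl("^@", lines)
  sym <- c(mat = "B", pat = "D", het = "H", unk = "U")
  declared <- character(0)
  for (ln in lines[meta_i]) {
    m <- regmatches(ln, regexec("^@([A-Za-z]+)[: \t]+(\\S+)", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(sym))
      declared[[m[3]]] <- unname(sym[m[2]])
  }
  ## undeclared roles fall back to the literal internal codes
  token_map <- declared
  for (code in setdiff(c("B", "D", "H", "U"), declared))
    if (!code %in% names(token_map)) token_map[[code]] <- code
  body <- which(keep & !meta_i)
  if (!length(body)) stop("no header line found")
  hdr <- strsplit(lines[body[1]], "\t|,")[[1]]
  hdr <- trimws(hdr)
  need <- c("Chr", "Locus", "cM", "Mb")
  if (!identical(hdr[1:4], need))
    stop("header must begin with columns: ", paste(need, collapse = ", "))
  strains <- hdr[-(1:4)]
  if (!length(strains)) stop("no strain columns in header")
  rows <- body[-1]
  if (!length(rows)) stop("no marker rows")
  chr <- character(length(rows)); locus <- character(length(rows))
  cM <- numeric(length(rows)); Mb <- numeric(length(rows))
  geno <- matrix(NA_character_, nrow = length(strains), ncol = length(rows),
                 dimnames = list(strains, NULL))
  for (k in seq_along(rows)) {
    i <- rows[k]
    f <- trimws(strsplit(lines[i], "\t|,")[[1]])
    if (length(f) != length(hdr))
      stop("line ", lineno[i], ": expected ", length(hdr), " fields, found ",
           length(f))
    chr[k] <- f[1]; locus[k] <- f[2]
    suppressWarnings({cm <- as.numeric(f[3]); mb <- as.numeric(f[4])})
    if (is.na(cm) || is.na(mb))
      stop("line ", lineno[i], ": non-numeric coordinate for marker ", f[2])
    cM[k] <- cm; Mb[k] <- mb
    tok <- f[-(1:4)]
    bad <- !(tok %in% names(token_map))
    if (any(bad))
      stop("line ", lineno[i], ": unknown allele token '",
           tok[which(bad)[1]], "' for marker ", f[2])
    geno[, k] <- unname(token_map[tok])
  }
  if (anyDuplicated(locus))
    stop("duplicate marker name: ",
         paste(unique(locus[duplicated(locus)]), collapse = ", "))
  colnames(geno) <- locus
  map <- gene_map(chr = chr, marker = locus, cM = cM, Mb = Mb)
  ## gene_map may reorder; keep genotype columns aligned
  new_geno_matrix(geno[, map$marker, drop = FALSE], map)
}

#' Write a genotype matrix in the .geno dialect
#'
#' @param geno a `geno_matrix`.
#' @param file output path or connection.
#' @param name optional population name written as `@name:` metadata.
#' @return the file path, invisibly.
#' @seealso [read_geno()]
#' @export
write_geno <- function(geno, file, name = "synthetic") {
  stopifnot(inherits(geno, "geno_matrix"))
  con <- if (is.character(file)) base::file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  writeLines(c(sprintf("@name:%s", name), "@type:riset",
               "@mat:B", "@pat:D", "@het:H", "@unk:U"), con)
  hdr <- paste(c("Chr", "Locus", "cM", "Mb", rownames(geno$geno)),
               collapse = "\t")
  writeLines(hdr, con)
  m <- geno$map
  for (k in seq_len(nrow(m))) {
    writeLines(paste(c(m$chr[k], m$marker[k],
                       sprintf("%.10g", m$cM[k]),
                       sprintf("%.10g", m$Mb[k]),
                       geno$geno[, m$marker[k]]), collapse = "\t"), con)
  }
  invisible(if (is.character(file)) file else NULL)
}
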