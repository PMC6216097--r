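#' Simulate recombinant inbred genotypes
#'
#' Generates a panel of fully inbred RI strains, each an independent mosaic
#' of the two parental alleles `B` and `D`. Along each chromosome the allele
#' sequence follows a two-state Markov chain: the first marker is `B` or `D`
#' with probability 1/2, and between adjacent markers the allele switches
#' with the RI-by-sib-mating discordance probability R = 4r/(1+6r), where r
#' is the Haldane recombination fraction implied by the cM gap (see
#' [ri_expand()], [haldane_r()]). No heterozygous or unknown calls are
#' emitted.
#'
#' @param n_strains number of RI strains (>= 2).
#' @param map a [gene_map()].
#' @param seed integer seed for reproducibility, or NULL.
#' @param strain_names optional strain names; default `RIS001`, ...
#' @return an object of class `geno_matrix`: a list with `geno` (character
#'   matrix, strains x markers, entries in `{"B","D"}`) and `map`.
#' @examples
#' g <- simulate_ri_genotypes(5, sim_map(2, 6, 50), seed = 1)
#' g$geno[, 1:4]
#' @export
simulate_ri_genotypes <- function(n_strains, map, seed = NULL,
                                  strain_names = NULL) {
  if (!inherits(map, "gene_map")) stop("'map' must be a gene_map")
  if (n_strains < 2) stop("n_strains must be >= 2")
  n_strains <- as.integer(n_strains)
  if (is.null(strain_names))
    strain_names <- sprintf("RIS%03d", seq_len(n_strains))
  with_seed(seed, {
    geno <- matrix(NA_integer_, nrow = n_strains, ncol = nrow(map),
                   dimnames = list(strain_names, map$marker))
    for (cc in unique(map$chr)) {
      idx <- which(map$chr == cc)
      ## allele coded 0 = B, 1 = D; vectorized over strains per marker
      cur <- as.integer(stats::runif(n_strains) < 0.5)
      geno[, idx[1L]] <- cur
      if (length(idx) > 1L) {
        gaps <- diff(map$cM[idx])
        R <- ri_expand(haldane_r(gaps))
        for (j in seq_along(gaps)) {
          flip <- stats::runif(n_strains) < R[j]
          cur <- ifelse(flip, 1L - cur, cur)
          geno[, idx[j + 1L]] <- cur
        }
      }
    }
    codes <- matrix(c("B", "D")[geno + 1L], nrow = n_strains,
                    dimnames = dimnames(geno))
    new_geno_matrix(codes, map)
  })
}

## internal constructor + validation shared with read_geno
new_geno_matrix <- function(codes, map) {
  stopifnot(is.matrix(codes), ncol(codes) == nrow(map))
  if (is.null(rownames(codes))) stop("strain names required")
  if (anyDuplicated(rownames(codes)))
    stop("duplicate strain name(s): ",
         paste(unique(rownames(codes)[duplicated(rownames(codes))]),
               collapse = ", "))
  bad <- setdiff(unique(as.vector(codes)), c("B", "D", "H", "U"))
  if (length(bad)) stop("unknown allele code(s): ", paste(bad, collapse = ", "))
  structure(list(geno = codes, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "strains x", ncol(x$geno), "markers on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  tab <- table(factor(as.vector(x$geno), levels = c("B", "D", "H", "U")))
  cat("allele codes:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Marker dosage codes from a genotype matrix
#'
#' Numeric coding used throughout mapping: `B` -> -1, `D` -> +1, `H` and `U`
#' -> NA (excluded from dosage computation).
#'
#' @param geno a `geno_matrix`.
#' @return numeric matrix, strains x markers.
#' @export
geno_codes <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  out <- matrix(NA_real_, nrow(geno$geno), ncol(geno$geno),
                dimnames = dimnames(geno$geno))
  out[geno$geno == "B"] <- -1
  out[geno$geno == "D"] <- 1
  out
}
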