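#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers with genetic (cM) and
#' physical (Mb) coordinates, grouped by chromosome. Marker order within a
#' chromosome must follow non-decreasing positions, and marker names must be
#' unique genome-wide.
#'
#' @param chr chromosome label per marker (character or factor).
#' @param marker marker names, unique genome-wide.
#' @param cM genetic positions in centimorgans, non-decreasing within
#'   chromosome.
#' @param Mb physical positions in megabases, non-decreasing within
#'   chromosome. Defaults to `cM / 2` (roughly the mouse genome-wide
#'   cM-to-Mb ratio) when not supplied.
#' @return a data frame of class `gene_map` with columns
#'   `marker`, `chr`, `cM`, `Mb`, ordered by chromosome then position.
#' @examples
#' gene_map(chr = c("1", "1", "2"), marker = c("m1", "m2", "m3"),
#'          cM = c(0, 10, 5), Mb = c(3, 22, 11))
#' @export
gene_map <- function(chr, marker, cM, Mb = NULL) {
  chr <- as.character(chr)
  marker <- as.character(marker)
  cM <- as.numeric(cM)
  if (is.null(Mb)) Mb <- cM / 2
  Mb <- as.numeric(Mb)
  n <- length(marker)
  if (length(chr) != n || length(cM) != n || length(Mb) != n)
    stop("chr, marker, cM and Mb must have equal length")
  if (n == 0L) stop("map must contain at least one marker")
  if (anyDuplicated(marker))
    stop("duplicate marker name(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (anyNA(cM) || anyNA(Mb)) stop("non-numeric or missing map coordinate")
  map <- data.frame(marker = marker, chr = chr, cM = cM, Mb = Mb,
                    stringsAsFactors = FALSE)
  ## stable grouping by chromosome; within-chromosome order is the caller's
  map <- map[order(match(map$chr, unique(chr))), , drop = FALSE]
  rownames(map) <- NULL
  for (cc in unique(map$chr)) {
    i <- map$chr == cc
    if (is.unsorted(map$cM[i]) || is.unsorted(map$Mb[i]))
      stop("non-monotone map positions on chromosome ", cc)
  }
  class(map) <- c("gene_map", "data.frame")
  map
}

#' Build a regular synthetic genetic map
#'
#' Convenience constructor for simulation studies: `n_chr` chromosomes each
#' carrying equally spaced markers.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers on each chromosome.
#' @param length_cM genetic length of each chromosome in cM.
#' @param mb_per_cm physical scale (Mb per cM); mouse-like default 2.
#' @return a [gene_map()].
#' @examples
#' sim_map(n_chr = 2, markers_per_chr = 5, length_cM = 40)
#' @export
sim_map <- function(n_chr = 10, markers_per_chr = 30, length_cM = 60,
                    mb_per_cm = 2) {
  stopifnot(n_chr >= 1, markers_per_chr >= 1, length_cM >= 0)
  chr <- rep(as.character(seq_len(n_chr)), each = markers_per_chr)
  pos <- if (markers_per_chr == 1L) 0
         else seq(0, length_cM, length.out = markers_per_chr)
  cM <- rep(pos, n_chr)
  marker <- sprintf("c%s_m%02d", chr, rep(seq_len(markers_per_chr), n_chr))
  gene_map(chr = chr, marker = marker, cM = cM, Mb = cM * mb_per_cm)
}

#' Haldane recombination fraction from a map distance
#'
#' @param d_cM map distance in centimorgans.
#' @return recombination fraction r = (1 - exp(-2 d)) / 2, d in Morgans.
#' @examples
#' haldane_r(0)     # 0
#' haldane_r(1e9)   # 0.5
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' RI-by-sib-mating expansion of a recombination fraction
#'
#' In recombinant inbred lines produced by sib mating, the chance that two
#' linked markers carry discordant parental alleles is expanded from the
#' single-generation recombination fraction r to R = 4r / (1 + 6r)
#' (Haldane-Waddington).
#'
#' @param r single-generation recombination fraction in \[0, 0.5\].
#' @return expanded discordance probability R.
#' @examples
#' ri_expand(0.5)  # 0.5: independence is preserved
#' ri_expand(0.1)  # 0.25
#' @export
ri_expand <- function(r) 4 * r / (1 + 6 * r)
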