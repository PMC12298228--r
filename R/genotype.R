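#' Genotype nomenclature and fitted rate constants
#'
#' Two genes modulate losartan kinetics here. CYP2C9 genotypes are written
#' as two star-alleles separated by "/", e.g. `"CYP2C9*1/CYP2C9*1"`. ABCB1
#' diplotypes are written as nucleotide pairs: 6-letter labels such as
#' `"CC/GG/CC"` give the two alleles at positions 1236, 2677 and 3435 in
#' that order; 4-letter labels such as `"GT/CT"` give positions 2677 and
#' 3435 only. Because the three coding SNPs are in strong linkage
#' disequilibrium, the 6-letter haplotypes `CC/GG/CC` and `TT/TT/TT` are
#' treated as equivalent to `GG/CC` and `TT/TT` respectively.
#'
#' @name genotypes
NULL

# Fitted genotype-specific rate constants (1/h). k_m quantifies CYP2C9
# conversion activity; k_ent_int quantifies ABCB1 efflux activity.
GENOTYPE_KM <- c("CYP2C9*1/CYP2C9*1" = 2.817,
                 "CYP2C9*3/CYP2C9*3" = 0.039)
GENOTYPE_KEI <- c("GG/CC" = 151.485,
                  "GT/CT" = 101.800,
                  "TT/TT" = 1.431e-12)
HAPLOTYPE_ALIAS <- c("CC/GG/CC" = "GG/CC", "TT/TT/TT" = "TT/TT")

#' Parse a genotype label
#'
#' @param label A genotype label (see [genotypes]); whitespace is trimmed,
#'   the label is otherwise case-sensitive.
#' @return A list of class `genotype` with elements `gene` ("CYP2C9" or
#'   "ABCB1"), `label` (canonical form), and either `alleles` (two
#'   star-alleles, sorted) or `positions` (named list of nucleotide pairs at
#'   positions 1236/2677/3435).
#' @export
#' @examples
#' parse_genotype("CC/GG/CC")
#' parse_genotype("GT/CT")
#' parse_genotype("CYP2C9*1/CYP2C9*1")
parse_genotype <- function(label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label)))
    stop("genotype label must be a non-empty string", call. = FALSE)
  lab <- trimws(label)
  if (grepl("^CYP2C9", lab)) {
    parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("malformed CYP2C9 label '", lab,
           "': expected two star-alleles separated by '/'", call. = FALSE)
    ok <- grepl("^CYP2C9\\*[0-9]+$", parts)
    if (!all(ok))
      stop("malformed CYP2C9 allele '", parts[!ok][1L], "' in '", lab, "'",
           call. = FALSE)
    alleles <- sort(parts)
    return(structure(list(gene = "CYP2C9", label = paste(alleles,
                                                         collapse = "/"),
                          alleles = alleles),
                     class = "genotype"))
  }
  fields <- strsplit(lab, "/", fixed = TRUE)[[1L]]
  if (!length(fields) %in% c(2L, 3L) || !all(nchar(fields) == 2L))
    stop("malformed ABCB1 label '", lab,
         "': expected 2 or 3 two-letter fields separated by '/'",
         call. = FALSE)
  nts <- strsplit(fields, "", fixed = TRUE)
  bad <- !vapply(nts, function(x) all(x %in% c("A", "C", "G", "T")), TRUE)
  if (any(bad))
    stop("invalid nucleotide in field '", fields[bad][1L], "' of '", lab,
         "'", call. = FALSE)
  pos <- if (length(fields) == 3L) c("1236", "2677", "3435") else
    c("2677", "3435")
  positions <- stats::setNames(nts, pos)
  structure(list(gene = "ABCB1", label = paste(fields, collapse = "/"),
                 positions = positions),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(x$gene, "genotype", x$label, "\n")
  if (x$gene == "CYP2C9") {
    cat("  alleles:", paste(x$alleles, collapse = ", "), "\n")
  } else {
    for (p in names(x$positions))
      cat(sprintf("  position %s: %s/%s\n", p, x$positions[[p]][1L],
                  x$positions[[p]][2L]))
  }
  invisible(x)
}

#' Fitted rate constants for a genotype
#'
#' Maps a supported genotype to its fitted rate constant: `k_m` (1/h,
#' losartan-to-E-3174 conversion) for the two homozygous CYP2C9 genotypes,
#' or `k_ent_int` (1/h, enterocyte efflux) for the three ABCB1 diplotypes.
#' Six-letter haplotypes map to their 4-letter equivalents (`CC/GG/CC` to
#' `GG/CC`, `TT/TT/TT` to `TT/TT`). Genotypes outside the fitted set
#' (heterozygous CYP2C9, the rare `CYP2C9*2` homozygote, uncommon ABCB1
#' diplotypes) raise an error; no interpolation is attempted.
#'
#' @param genotype A label or a parsed [parse_genotype()] object.
#' @return A named list with elements `gene`, `label` (canonical 4-letter /
#'   star-allele form) and one of `k_m` or `k_ent_int`.
#' @export
#' @examples
#' lookup_rate_constants("CYP2C9*1/CYP2C9*1")$k_m
#' lookup_rate_constants("TT/TT")$k_ent_int
lookup_rate_constants <- function(genotype) {
  g <- if (inherits(genotype, "genotype")) genotype else
    parse_genotype(genotype)
  if (g$gene == "CYP2C9") {
    if (!g$label %in% names(GENOTYPE_KM))
      stop("unsupported CYP2C9 genotype '", g$label,
           "': fitted constants exist only for the *1/*1 and *3/*3 ",
           "homozygotes", call. = FALSE)
    return(list(gene = "CYP2C9", label = g$label,
                k_m = unname(GENOTYPE_KM[g$label])))
  }
  lab <- g$label
  if (lab %in% names(HAPLOTYPE_ALIAS)) lab <- HAPLOTYPE_ALIAS[[lab]]
  if (!lab %in% names(GENOTYPE_KEI))
    stop("unsupported ABCB1 genotype '", g$label,
         "': fitted constants exist only for GG/CC, GT/CT, TT/TT ",
         "(and the CC/GG/CC, TT/TT/TT haplotypes)", call. = FALSE)
  list(gene = "ABCB1", label = lab,
       k_ent_int = unname(GENOTYPE_KEI[lab]))
}

#' Supported genotype labels
#'
#' @return Character vector of all labels accepted by
#'   [lookup_rate_constants()].
#' @export
supported_genotypes <- function() {
  c(names(GENOTYPE_KM), names(GENOTYPE_KEI), names(HAPLOTYPE_ALIAS))
}

#' Model parameters for a genotype
#'
#' Returns `base` with the genotype-specific rate constant substituted. For
#' an ABCB1 genotype, `k_ent_int` is set and the CYP2C9 background is
#' assumed wild type (`k_m` for *1/*1). For a CYP2C9 genotype, `k_m` is set
#' and the ABCB1 background is assumed GT/CT, the most frequent diplotype in
#' the population the constants were fitted to.
#'
#' @param genotype A label or parsed genotype.
#' @param base A [losartan_params()] object to modify.
#' @return A `losartan_params` object.
#' @export
#' @examples
#' genotype_params("TT/TT")$k_ent_int
genotype_params <- function(genotype, base = losartan_params()) {
  rc <- lookup_rate_constants(genotype)
  if (rc$gene == "CYP2C9") {
    set_params(base, k_m = rc$k_m,
               k_ent_int = unname(GENOTYPE_KEI[["GT/CT"]]))
  } else {
    set_params(base, k_ent_int = rc$k_ent_int,
               k_m = unname(GENOTYPE_KM[["CYP2C9*1/CYP2C9*1"]]))
  }
}

#' Genotype constants table
#'
#' The shipped versioned table of fitted genotype-specific rate constants,
#' also available as JSON at
#' `system.file("extdata", "genotype_constants.json", package =
#' "losartanpkpd")`.
#'
#' @return A data frame with columns `gene`, `genotype`, `parameter`,
#'   `value_per_h`.
#' @export
genotype_constants <- function() {
  data.frame(
    gene = c("CYP2C9", "CYP2C9", "ABCB1", "ABCB1", "ABCB1"),
    genotype = c(names(GENOTYPE_KM), names(GENOTYPE_KEI)),
    parameter = c("k_m", "k_m", "k_ent_int", "k_ent_int", "k_ent_int"),
    value_per_h = unname(c(GENOTYPE_KM, GENOTYPE_KEI)),
    stringsAsFactors = FALSE)
}
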