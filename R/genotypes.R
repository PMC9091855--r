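#' Construct a GenotypeSet
#'
#' Container for biallelic autosomal SNP genotypes: an individuals-by-SNP
#' matrix of reference-allele counts (0/1/2, `NA` = missing), per-SNP allele
#' labels, an optional pair of phased haplotype matrices and an optional
#' genetic map.
#'
#' @param geno Integer matrix, individuals x SNPs, entries in \{0,1,2,NA\};
#'   rownames are individual ids, colnames SNP ids.
#' @param alleles Data frame with columns `snp_id`, `ref`, `alt`. `ref` is the
#'   counted allele.
#' @param haplotypes Optional list of two 0/1 matrices (`hap1`, `hap2`) of the
#'   same dimension as `geno`; their sum must equal `geno` wherever `geno` is
#'   non-missing.
#' @param map Optional `GeneticMap` (see [genetic_map()]) covering `colnames(geno)`.
#' @return An object of class `GenotypeSet`.
#' @export
genotype_set <- function(geno, alleles = NULL, haplotypes = NULL, map = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop("geno must carry individual ids as rownames and SNP ids as colnames")
  }
  if (anyDuplicated(rownames(geno))) stop("duplicate individual ids in genotype matrix")
  if (anyDuplicated(colnames(geno))) stop("duplicate SNP ids in genotype matrix")
  rng <- range(geno, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("genotype counts must lie in {0,1,2}")
  }
  if (is.null(alleles)) {
    alleles <- data.frame(snp_id = colnames(geno), ref = "A", alt = "B",
                          stringsAsFactors = FALSE)
  }
  stopifnot(identical(alleles$snp_id, colnames(geno)))
  if (!is.null(haplotypes)) {
    stopifnot(length(haplotypes) == 2L)
    h <- haplotypes[[1]] + haplotypes[[2]]
    ok <- is.na(geno) | h == geno
    if (!all(ok)) stop("phased haplotypes do not sum to genotype counts")
  }
  if (!is.null(map)) {
    stopifnot(identical(map$snp_id, colnames(geno)))
  }
  structure(list(geno = geno, alleles = alleles, haplotypes = haplotypes,
                 map = map),
            class = "GenotypeSet")
}

#' @export
#' @method print GenotypeSet
print.GenotypeSet <- function(x, ...) {
  cat(sprintf("GenotypeSet: %d individuals x %d SNPs (%s phased, %s map)\n",
              nrow(x$geno), ncol(x$geno),
              if (is.null(x$haplotypes)) "not" else "",
              if (is.null(x$map)) "no" else "with"))
  invisible(x)
}

#' @export
#' @method dim GenotypeSet
dim.GenotypeSet <- function(x) dim(x$geno)

#' Subset a GenotypeSet by individuals and/or SNPs
#'
#' @param g A `GenotypeSet`.
#' @param ids Character vector of individual ids to keep (default all).
#' @param snps Character vector of SNP ids to keep (default all).
#' @return The subsetted `GenotypeSet`.
#' @export
subset_genotypes <- function(g, ids = rownames(g$geno), snps = colnames(g$geno)) {
  ri <- match(ids, rownames(g$geno))
  ci <- match(snps, colnames(g$geno))
  if (anyNA(ri)) stop("unknown individual ids: ", paste(ids[is.na(ri)][1:min(3, sum(is.na(ri)))], collapse = ", "))
  if (anyNA(ci)) stop("unknown SNP ids")
  haps <- g$haplotypes
  if (!is.null(haps)) haps <- lapply(haps, function(h) h[ri, ci, drop = FALSE])
  map <- g$map
  if (!is.null(map)) {
    map <- map[ci, , drop = FALSE]
    map <- recompute_last_intervals(map)
  }
  genotype_set(g$geno[ri, ci, drop = FALSE],
               alleles = g$alleles[ci, , drop = FALSE],
               haplotypes = haps, map = map)
}

#' Construct a genetic map
#'
#' @param chr Chromosome id per SNP.
#' @param snp_id SNP ids, unique, ordered by (chromosome, position).
#' @param pos Physical or map position within chromosome (ascending within
#'   chromosome).
#' @param rec_next Recombination fraction between each SNP and the next SNP in
#'   order, in `[0, 0.5]`; the last SNP of every chromosome carries 0.5 so that
#'   chromosomes segregate independently. If `NULL`, computed from `cm` via
#'   Haldane's map function.
#' @param cm Optional inter-SNP distance in centimorgans (to the next SNP);
#'   converted with `r = (1 - exp(-2 d / 100)) / 2`.
#' @return A `GeneticMap` data frame with columns `chr`, `snp_id`, `pos`,
#'   `rec_next`.
#' @export
genetic_map <- function(chr, snp_id, pos, rec_next = NULL, cm = NULL) {
  if (is.null(rec_next)) {
    if (is.null(cm)) stop("supply rec_next or cm")
    rec_next <- (1 - exp(-2 * cm / 100)) / 2
  }
  map <- data.frame(chr = as.character(chr), snp_id = as.character(snp_id),
                    pos = as.numeric(pos), rec_next = as.numeric(rec_next),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in map")
  if (is.unsorted(order(map$chr, map$pos))) {
    map <- map[order(map$chr, map$pos), , drop = FALSE]
  }
  map <- recompute_last_intervals(map)
  if (any(map$rec_next < 0 | map$rec_next > 0.5)) {
    stop("recombination fractions must lie in [0, 0.5]")
  }
  rownames(map) <- NULL
  class(map) <- c("GeneticMap", "data.frame")
  map
}

# last SNP of each chromosome must carry r = 0.5 (independent segregation)
recompute_last_intervals <- function(map) {
  n <- nrow(map)
  last <- c(map$chr[-n] != map$chr[-1], TRUE)
  map$rec_next[last] <- 0.5
  map
}

#' Per-interval template-switch probabilities for meiosis
#'
#' @param map A `GeneticMap`.
#' @return Numeric vector of length `nrow(map)`: element j is the probability
#'   of switching parental template between SNP j-1 and SNP j (element 1 is 0;
#'   the starting template is drawn at random).
#' @keywords internal
switch_probs <- function(map) {
  c(0, map$rec_next[-nrow(map)])
}

#' Read genotypes from standard formats
#'
#' Supported dialects: PLINK text (`.ped` + `.map` pair), a headered
#' id-by-SNP count-matrix TSV (first column `id`, remaining columns SNP ids,
#' entries 0/1/2 or NA), and VCF (biallelic records only; requires the vcfR
#' package). Counts are oriented to a declared reference allele per SNP: by
#' default the alphabetically first allele observed; multi-allelic sites are
#' skipped with a warning.
#'
#' @param path For `plink_text`, the path prefix or the `.ped` file; otherwise
#'   the file itself.
#' @param format One of `"plink_text"`, `"matrix"`, `"vcf"`.
#' @return A `GenotypeSet`.
#' @export
read_genotypes <- function(path, format = c("matrix", "plink_text", "vcf")) {
  format <- match.arg(format)
  switch(format,
         matrix = read_genotypes_matrix(path),
         plink_text = read_genotypes_plink(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_matrix <- function(path) {
  df <- read_table_auto(path)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed genotype matrix file: ", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("id collision in genotype matrix: ",
                               ids[duplicated(ids)][1])
  g <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(g) <- "integer")
  rownames(g) <- ids
  genotype_set(g)
}

#' Write a GenotypeSet in the count-matrix TSV dialect
#'
#' @param g A `GenotypeSet`.
#' @param path Output path.
#' @export
write_genotypes_matrix <- function(g, path) {
  df <- data.frame(id = rownames(g$geno), g$geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_genotypes_plink <- function(path) {
  ped_file <- if (grepl("\\.ped$", path)) path else paste0(path, ".ped")
  map_file <- sub("\\.ped$", ".map", ped_file)
  if (!file.exists(ped_file)) stop("file not found: ", ped_file)
  if (!file.exists(map_file)) stop("file not found: ", map_file)
  map <- utils::read.table(map_file, header = FALSE, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chr", "snp_id", "cm", "pos")
  ped <- utils::read.table(ped_file, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(ped) == 0) stop("empty .ped file")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop(".ped column count does not match .map SNP count")
  }
  ids <- ped[[2]]
  if (anyDuplicated(ids)) stop("id collision in .ped file: ", ids[duplicated(ids)][1])
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  n <- length(ids)
  geno <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp_id))
  ref <- alt <- character(m)
  keep <- logical(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alle <- sort(setdiff(unique(obs), "0"))
    if (length(alle) > 2) {
      warning("skipping multi-allelic SNP ", map$snp_id[j])
      next
    }
    if (length(alle) == 0) next
    keep[j] <- TRUE
    ref[j] <- alle[1]
    alt[j] <- if (length(alle) == 2) alle[2] else "."
    miss <- a1[, j] == "0" | a2[, j] == "0"
    cnt <- (a1[, j] == ref[j]) + (a2[, j] == ref[j])
    cnt[miss] <- NA_integer_
    geno[, j] <- cnt
  }
  if (!any(keep)) stop("no usable biallelic SNPs in ", ped_file)
  alleles <- data.frame(snp_id = map$snp_id[keep], ref = ref[keep],
                        alt = alt[keep], stringsAsFactors = FALSE)
  gm <- genetic_map(chr = map$chr[keep], snp_id = map$snp_id[keep],
                    pos = map$pos[keep],
                    cm = interval_cm(map$chr[keep], map$cm[keep]))
  genotype_set(geno[, keep, drop = FALSE], alleles = alleles, map = gm)
}

# cM to next SNP from cumulative positions; last interval per chromosome
# is overwritten with r = 0.5 downstream
interval_cm <- function(chr, cm) {
  cm <- as.numeric(cm)
  d <- c(pmax(cm[-1] - cm[-length(cm)], 0), 0)
  d[c(chr[-length(chr)] != chr[-1], TRUE)] <- 0
  d
}

#' Write a GenotypeSet as PLINK text .ped/.map
#'
#' @param g A `GenotypeSet` (map required).
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @export
write_genotypes_plink <- function(g, prefix) {
  if (is.null(g$map)) stop("a GeneticMap is required to write PLINK files")
  geno <- g$geno
  n <- nrow(geno); m <- ncol(geno)
  ref <- g$alleles$ref; alt <- g$alleles$alt
  alt[alt == "."] <- ref[alt == "."]
  al1 <- al2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    cnt <- geno[, j]
    al1[, j] <- ifelse(is.na(cnt), "0", ifelse(cnt >= 1, ref[j], alt[j]))
    al2[, j] <- ifelse(is.na(cnt), "0", ifelse(cnt == 2, ref[j], alt[j]))
  }
  inter <- matrix("", n, 2 * m)
  inter[, 2 * seq_len(m) - 1] <- al1
  inter[, 2 * seq_len(m)] <- al2
  out <- cbind(rownames(geno), rownames(geno), "0", "0", "0", "-9", inter)
  utils::write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # rebuild cumulative cM within chromosome via Haldane's inverse map function
  d_prev <- c(0, -50 * log(pmax(1 - 2 * g$map$rec_next[-m], 1e-12)))
  d_prev[c(FALSE, g$map$chr[-1] != g$map$chr[-m])] <- 0
  cum_cm <- stats::ave(d_prev, g$map$chr, FUN = cumsum)
  mp <- data.frame(g$map$chr, g$map$snp_id, cum_cm, g$map$pos)
  utils::write.table(mp, paste0(prefix, ".map"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  if (any(!biallelic)) warning("skipping ", sum(!biallelic), " non-biallelic VCF record(s)")
  if (!any(biallelic)) stop("no biallelic SNPs in VCF")
  gt <- vcfR::extract.gt(v)[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  snp_ids <- fix[, "ID"]
  no_id <- is.na(snp_ids) | snp_ids == "."
  snp_ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  ids <- colnames(gt)
  if (anyDuplicated(ids)) stop("id collision in VCF sample names")
  # count REF alleles; GT like 0/1, 0|1, ./.
  cnt_ref <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(z) {
      if (any(z == "." | is.na(z))) NA_integer_ else sum(z == "0")
    }, integer(1))
  }
  geno <- t(apply(gt, 1, cnt_ref))
  geno[is.na(gt)] <- NA_integer_
  geno <- t(geno)  # individuals x SNPs
  dimnames(geno) <- list(ids, snp_ids)
  alleles <- data.frame(snp_id = snp_ids, ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  genotype_set(geno, alleles = alleles)
}
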