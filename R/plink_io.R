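#' Write a genotype matrix as PLINK text files
#'
#' Produces `<prefix>.ped` (one row per subject: family id, subject id,
#' father, mother, sex, phenotype, then two whitespace-separated allele
#' calls per SNP; missing genotypes as `0 0`) and `<prefix>.map`
#' (chromosome, SNP id, genetic distance 0, bp position).
#'
#' @param g A [genotype_matrix()] whose annotations carry `minor` and
#'   `major` allele letters.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_ped <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$snps$minor) || is.null(g$snps$major))
    stop("annotations must carry 'minor' and 'major' allele letters")
  n <- nrow(g$values); p <- ncol(g$values)
  allele <- matrix("0", n, 2L * p)
  for (k in seq_len(p)) {
    cnt <- g$values[, k]
    a1 <- ifelse(is.na(cnt), "0", ifelse(cnt >= 1, g$snps$minor[k], g$snps$major[k]))
    a2 <- ifelse(is.na(cnt), "0", ifelse(cnt == 2, g$snps$minor[k], g$snps$major[k]))
    allele[, 2L * k - 1L] <- a1
    allele[, 2L * k] <- a2
  }
  ped <- cbind(g$subject_ids, g$subject_ids, "0", "0", "0", "-9", allele)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chr = g$snps$chr, id = g$snps$id, cm = 0, bp = g$snps$bp)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK text genotypes into a genotype matrix
#'
#' Parses `.ped`/`.map` pairs, coding each SNP as the count of its minor
#' allele. `0` allele calls mark missing genotypes. When `minor_alleles` is
#' not supplied, the minor allele is inferred per SNP as the less frequent
#' allele in the sample (ties broken toward the alphabetically smaller
#' letter).
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @param minor_alleles Optional named character vector (SNP id -> minor
#'   allele letter) fixing the counting orientation.
#' @return A [genotype_matrix()].
#' @export
read_ped <- function(ped_path, map_path, minor_alleles = NULL) {
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           col.names = c("chr", "id", "cm", "bp"))
  ped <- utils::read.table(ped_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  p <- nrow(map)
  if (ncol(ped) != 6 + 2 * p)
    stop("ped/map mismatch: expected ", 6 + 2 * p, " columns, found ", ncol(ped))
  subject_ids <- ped[[2]]
  n <- nrow(ped)
  values <- matrix(NA_real_, n, p)
  minor <- character(p); major <- character(p)
  for (k in seq_len(p)) {
    a1 <- ped[[6 + 2 * k - 1]]
    a2 <- ped[[6 + 2 * k]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) == 0) { minor[k] <- major[k] <- NA; next }
    mk <- if (!is.null(minor_alleles) && map$id[k] %in% names(minor_alleles)) {
      as.character(minor_alleles[[map$id[k]]])
    } else {
      freq <- vapply(alleles, function(a) sum(a1[!miss] == a) + sum(a2[!miss] == a),
                     numeric(1))
      alleles[order(freq, alleles)][1]
    }
    minor[k] <- mk
    major[k] <- if (length(alleles) > 1) setdiff(alleles, mk)[1] else mk
    values[, k] <- (a1 == mk) + (a2 == mk)
    values[miss, k] <- NA
  }
  genotype_matrix(values,
                  data.frame(id = map$id, chr = map$chr, bp = map$bp,
                             minor = minor, major = major,
                             stringsAsFactors = FALSE),
                  subject_ids = subject_ids)
}

#' Read a delimited additive genotype matrix
#'
#' Alternative plain-matrix input: a delimited file of minor-allele counts
#' with subject ids in the first column and SNP ids as the header, plus a
#' SNP annotation table with `id`, `chr`, `bp` columns.
#'
#' @param matrix_path Delimited counts file (csv by default).
#' @param snp_info_path SNP annotation CSV.
#' @param sep Field separator (default ",").
#' @return A [genotype_matrix()].
#' @export
read_geno_table <- function(matrix_path, snp_info_path, sep = ",") {
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- tab[[1]]
  values <- as.matrix(tab[, -1, drop = FALSE])
  info <- utils::read.csv(snp_info_path, stringsAsFactors = FALSE)
  info <- info[match(colnames(values), info$id), ]
  genotype_matrix(values, info, subject_ids = ids)
}
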