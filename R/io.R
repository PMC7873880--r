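# Genotype panel serialization: PLINK1 binary trio (.bed/.bim/.fam,
# SNP-major) and VCFv4 with GT fields.  The counted allele (A1 in .bim, ALT
# in VCF) is the generation-time minor allele, so dosages round-trip
# unchanged.  Phenotype tables use the whitespace-delimited
# family/individual/trait layout that GEMMA and .fam files share.

#' Write a genotype panel to PLINK1 or VCF
#'
#' The format is chosen from the path: `*.vcf` writes VCFv4.2 with GT
#' fields; anything else is treated as a PLINK prefix and writes the
#' `.bed`/`.bim`/`.fam` trio (SNP-major `.bed`).
#'
#' @param G A `genotype_panel`.
#' @param path Output path (`.vcf` file or PLINK prefix).
#' @return `path`, invisibly.
#' @export
write_panel <- function(G, path) {
  validate_panel(G)
  if (grepl("\\.vcf$", path)) write_vcf_panel(G, path) else write_plink_panel(G, path)
  invisible(path)
}

#' Read a genotype panel from PLINK1 or VCF
#'
#' Inverse of [write_panel()].  Dosages count the A1 (PLINK) / ALT (VCF)
#' allele.  Malformed records (dosage outside {0,1,2}, non-monotone
#' positions) raise errors naming the offending record.
#'
#' @param path `.vcf` file or PLINK prefix (with or without `.bed`).
#' @return A `genotype_panel`.
#' @export
read_panel <- function(path) {
  if (grepl("\\.vcf$", path)) read_vcf_panel(path)
  else read_plink_panel(sub("\\.bed$", "", path))
}

write_plink_panel <- function(G, prefix) {
  map <- G$map
  bim <- data.frame(chr = map$chr, id = map$id, cm = 0, pos = map$pos,
                    a1 = map$a1, a2 = map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = G$ids, iid = G$ids, pat = 0, mat = 0, sex = 0, phen = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(G$dosages)
  # 2-bit codes per individual: dosage of A1 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, ncol(G$dosages))
  code[G$dosages == 2] <- 0L
  code[G$dosages == 1] <- 2L
  code[is.na(G$dosages)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad) code <- rbind(code, matrix(0L, pad, ncol(code)))
  shift <- rep(c(1L, 4L, 16L, 64L), bytes_per_snp)
  packed <- code * shift
  grp <- rep(seq_len(bytes_per_snp), each = 4)
  bytes <- vapply(seq_len(ncol(code)),
                  function(j) as.raw(tapply(packed[, j], grp, sum)),
                  raw(bytes_per_snp))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.vector(bytes), con)
  invisible(prefix)
}

read_plink_panel <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b)
    stop_invalid("%s.bed: not a PLINK1 .bed file (bad magic number)", prefix)
  if (raw[3] != 0x01) stop_invalid("%s.bed: not SNP-major", prefix)
  body <- as.integer(raw[-(1:3)])
  bytes_per_snp <- ceiling(n / 4)
  if (length(body) != bytes_per_snp * m)
    stop_invalid("%s.bed: expected %d data bytes, found %d",
                 prefix, bytes_per_snp * m, length(body))
  dos_map <- c(2L, NA_integer_, 1L, 0L)  # codes 00, 01, 10, 11
  X <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    b <- body[(j - 1) * bytes_per_snp + seq_len(bytes_per_snp)]
    codes <- c(rbind(b %% 4, (b %/% 4) %% 4, (b %/% 16) %% 4, b %/% 64))
    X[, j] <- dos_map[codes[seq_len(n)] + 1L]
  }
  map <- data.frame(id = bim$id, chr = bim$chr, pos = bim$pos,
                    a1 = bim$a1, a2 = bim$a2, stringsAsFactors = FALSE)
  G <- new_genotype_panel(X, map, as.character(fam[[2]]))
  validate_panel(G)
  G
}

write_vcf_panel <- function(G, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=pleiolink",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$ids), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(G$map)), function(j) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(G$map$chr[j], G$map$pos[j], G$map$id[j], G$map$a2[j], G$map$a1[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  to_dosage <- function(g, rec) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!all(alleles %in% c("0", "1")))
      stop_invalid("record %s: genotype '%s' is not biallelic 0/1", rec, g)
    sum(alleles == "1")
  }
  m <- nrow(gt)
  ids <- colnames(gt)
  X <- matrix(NA_integer_, length(ids), m)
  for (j in seq_len(m)) {
    X[, j] <- vapply(gt[j, ], to_dosage, integer(1), rec = fix[j, "ID"])
  }
  map <- data.frame(id = fix[, "ID"], chr = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    a1 = fix[, "ALT"], a2 = fix[, "REF"],
                    stringsAsFactors = FALSE)
  G <- new_genotype_panel(X, map, ids)
  validate_panel(G)
  G
}

#' Write a two-trait phenotype table
#'
#' Whitespace-delimited columns: family id, individual id, trait 1, trait 2
#' (GEMMA/.fam-compatible layout, no header).
#'
#' @param ids Individual ids.
#' @param y1,y2 Phenotype vectors.
#' @param path Output file.
#' @export
write_phenotypes <- function(ids, y1, y2, path) {
  utils::write.table(data.frame(ids, ids, y1, y2), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}

#' Write a QTN ledger for a set of replicates
#'
#' Tab-separated table: replicate, trait, architecture, marker id,
#' chromosome, position, realized MAF, realized QTN-pair r2.
#'
#' @param assignments List of `qtn_assignment`s (one per replicate).
#' @param path Output file.
#' @export
write_qtn_ledger <- function(assignments, path) {
  rows <- do.call(rbind, lapply(seq_along(assignments), function(i) {
    a <- assignments[[i]]
    data.frame(replicate = i, trait = 1:2, architecture = a$architecture,
               id = c(a$qtn_trait1$id, a$qtn_trait2$id),
               chr = c(a$qtn_trait1$chr, a$qtn_trait2$chr),
               pos = c(a$qtn_trait1$pos, a$qtn_trait2$pos),
               maf = c(a$realized_maf_1, a$realized_maf_2),
               r2 = a$realized_r2 %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
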