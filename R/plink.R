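# PLINK 1 binary genotype I/O.
#
# bed layout (SNP-major): 3 magic bytes 0x6c 0x1b 0x01, then ceil(n/4) bytes
# per SNP, two bits per individual starting at the low bits of each byte.
# 2-bit codes (dosage = count of allele 1 from the bim line):
#   00 = hom allele1 (dosage 2), 10 = het (1), 11 = hom allele2 (0),
#   01 = missing.

.bed_code <- function(d) {                     # dosage/NA -> 2-bit code
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  code
}

.bed_decode <- c(2L, NA_integer_, 1L, 0L)      # code 0..3 -> dosage

#' Write a genotype panel as PLINK 1 bed/bim/fam
#'
#' @param panel a \code{genotype_panel}.
#' @param prefix output path prefix; \code{prefix.bed/.bim/.fam} are written.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stop_if_not_panel(panel)
  n <- length(panel$ids)
  m <- ncol(panel$X)
  if (n < 1 || m < 1) stop("empty panel", call. = FALSE)
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("unwritable path: ", dir, call. = FALSE)

  # fam: FID IID father mother sex(1=male,2=female) phenotype
  is_child <- !is.na(panel$role) & panel$role == "child"
  pid <- ifelse(is_child, paste0(panel$fid, "_FA"), "0")
  mid <- ifelse(is_child, paste0(panel$fid, "_MO"), "0")
  fam <- data.frame(panel$fid, panel$ids, pid, mid,
                    ifelse(panel$sex == 1, 1L, 2L), -9L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(panel$snps$chr, panel$snps$id, 0L, panel$snps$pos,
                    panel$snps$a1, panel$snps$a2)
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  npad <- 4 * ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  codes <- matrix(3L, nrow = npad, ncol = m)   # pad bits: 11 (hom allele2)
  codes[seq_len(n), ] <- apply(panel$X, 2, .bed_code)
  i1 <- seq(1, npad, by = 4)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1, , drop = FALSE] +
    16L * codes[i1 + 2, , drop = FALSE] + 64L * codes[i1 + 3, , drop = FALSE]
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read PLINK 1 bed/bim/fam into a genotype panel
#'
#' Family roles are inferred from the fam parental-id columns where possible
#' (rows listed as someone's father/mother, rows with named parents as
#' children); otherwise NA.
#'
#' @param prefix path prefix of the \code{.bed/.bim/.fam} triplet.
#' @return a \code{genotype_panel} (without transmission records).
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "a1", "a2"))
  n <- nrow(fam)
  m <- nrow(bim)
  bpl <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + bpl * m + 1)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]),
                                    c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK 1 bed file", call. = FALSE)
  }
  if (length(raw) != 3 + bpl * m) {
    stop(sprintf("bed payload has %d bytes, expected %d (n=%d, m=%d)",
                 length(raw) - 3, bpl * m, n, m), call. = FALSE)
  }
  b <- as.integer(raw[-(1:3)])
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  dim(codes) <- c(4 * bpl, m)
  X <- matrix(.bed_decode[codes[seq_len(n), , drop = FALSE] + 1L], n, m)
  rownames(X) <- fam$iid
  colnames(X) <- bim$id

  role <- rep(NA_character_, n)
  role[fam$iid %in% fam$pid] <- "father"
  role[fam$iid %in% fam$mid] <- "mother"
  role[fam$pid != "0" | fam$mid != "0"] <- "child"
  p <- colMeans(X, na.rm = TRUE) / 2
  snps <- data.frame(id = bim$id, chr = bim$chr, pos = bim$pos,
                     a1 = bim$a1, a2 = bim$a2, freq1 = p,
                     stringsAsFactors = FALSE)
  structure(list(
    ids = fam$iid, fid = fam$fid, role = role,
    sex = ifelse(fam$sex == 1, 1L, 0L), subpop = rep(1L, n),
    X = X, snps = snps, transmission = NULL, params = NULL
  ), class = "genotype_panel")
}
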