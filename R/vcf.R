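## VCF import/export of call sets, built on vcfR.  Genotypes are diploid
## biallelic: 0/0, 0/1, 1/1 or ./.; the caller label travels in a
## ##source header line.

geno_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

gt_to_geno <- function(gt) {
  gt0 <- gsub("\\|", "/", gt)
  g <- rep(NA_integer_, length(gt0))
  g[gt0 == "0/0"] <- 0L
  g[gt0 %in% c("0/1", "1/0")] <- 1L
  g[gt0 == "1/1"] <- 2L
  bad <- !is.na(gt0) & !(gt0 %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(bad)) {
    stop("unsupported genotype code(s): ",
         paste(unique(gt0[bad]), collapse = ", "),
         " (only biallelic diploid GT values are registered)")
  }
  g
}

#' Write a call set to VCF
#'
#' Emits a VCF 4.2 file with GT, DP and (when present) GQ format fields;
#' the caller label is recorded in a `##source` header line.  A `.gz`
#' suffix produces a bgzip-style compressed file, otherwise plain text.
#'
#' @param callset A [callset()].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path) {
  stopifnot(inherits(callset, "callset"))
  s <- callset$sites
  n <- nrow(s)
  fix <- cbind(CHROM = as.character(s$chrom), POS = as.character(s$pos),
               ID = rep(".", n), REF = s$ref, ALT = s$alt,
               QUAL = rep(".", n), FILTER = rep(".", n),
               INFO = rep(".", n))
  has_gq <- !is.null(callset$gq)
  fmt <- if (has_gq) "GT:DP:GQ" else "GT:DP"
  cell <- function(j) {
    gt <- geno_to_gt(callset$geno[, j])
    dp <- callset$dp[, j]
    dp_s <- ifelse(is.na(dp), ".", as.character(dp))
    if (has_gq) {
      gq <- callset$gq[, j]
      gq_s <- ifelse(is.na(gq), ".", as.character(gq))
      paste(gt, dp_s, gq_s, sep = ":")
    } else {
      paste(gt, dp_s, sep = ":")
    }
  }
  if (is.null(callset$dp)) {
    fmt <- "GT"
    cell <- function(j) geno_to_gt(callset$geno[, j])
  }
  gt <- cbind(FORMAT = rep(fmt, n),
              vapply(seq_along(callset$individuals), cell, character(n)))
  colnames(gt) <- c("FORMAT", callset$individuals)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=", callset$caller),
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
            '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  obj <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(obj, file = path)
  } else {
    tmp <- tempfile(fileext = ".vcf.gz")
    on.exit(unlink(tmp))
    vcfR::write.vcf(obj, file = tmp)
    writeLines(readLines(gzfile(tmp)), path)
  }
  invisible(path)
}

#' Read a call set from VCF
#'
#' Parses a diploid biallelic VCF (GT required; DP and GQ picked up when
#' present).  `./.` becomes a missing call.  Sites with more than one ALT
#' allele, or GT codes beyond the registered allele pair, are an error.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @param caller Caller label; defaults to the `##source` header line when
#'   present.
#' @return A [callset()].
#' @export
read_vcf <- function(path, caller = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic ALT field; only biallelic sites are supported")
  }
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = alt,
                      stringsAsFactors = FALSE)
  fmt <- unique(v@gt[, "FORMAT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(gt_to_geno(gt), nrow = nrow(sites),
                 dimnames = list(NULL, colnames(gt)))
  grab_num <- function(el) {
    if (!any(grepl(el, fmt))) return(NULL)
    m <- suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    matrix(as.integer(m), nrow = nrow(sites), dimnames = list(NULL, colnames(m)))
  }
  dp <- grab_num("DP")
  gq <- grab_num("GQ")
  if (is.null(caller)) {
    src <- grep("^##source=", v@meta, value = TRUE)
    caller <- if (length(src)) sub("^##source=", "", src[1]) else "unknown"
  }
  callset(sites, geno, dp = dp, gq = gq, caller = caller)
}
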