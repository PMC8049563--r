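#' Polarize one site's diploid genotypes against the ancestral allele
#'
#' Converts two diploid genotype calls into derived-allele counts given the
#' ancestral allele. A site is valid only if every observed allele is either
#' the ancestral allele or one single derived allele (bi-allelic,
#' infinite-sites assumption); missing calls or a third allele invalidate the
#' site.
#'
#' @param gt1,gt2 genotype of the individual from population 1 / 2, as a
#'   string like `"A/G"` (separator `/` or `|`) or a character vector of two
#'   alleles.
#' @param ancestral the ancestral allele (single character).
#' @return list with `d1`, `d2` (derived counts, `NA` when invalid), `valid`,
#'   and `reason` (`"ok"`, `"missing_genotype"`, `"multiallelic"`,
#'   `"ancestral_not_seen"`).
#' @examples
#' polarize_site("A/G", "G/G", "A")  # d1 = 1, d2 = 2
#' @export
polarize_site <- function(gt1, gt2, ancestral) {
  split_gt <- function(gt) {
    if (length(gt) == 1L) gt <- strsplit(gt, "[/|]")[[1L]]
    toupper(trimws(gt))
  }
  a1 <- split_gt(gt1)
  a2 <- split_gt(gt2)
  anc <- toupper(trimws(ancestral))
  invalid <- function(reason) list(d1 = NA_integer_, d2 = NA_integer_,
                                   valid = FALSE, reason = reason)
  alleles <- c(a1, a2)
  if (length(a1) != 2L || length(a2) != 2L || anyNA(alleles) ||
      any(alleles %in% c("", ".", "N")) || is.na(anc) || !nzchar(anc)) {
    return(invalid("missing_genotype"))
  }
  derived <- setdiff(unique(alleles), anc)
  if (length(derived) > 1L) return(invalid("multiallelic"))
  list(d1 = sum(a1 != anc), d2 = sum(a2 != anc), valid = TRUE, reason = "ok")
}

#' Read / write a per-site genotype table
#'
#' The table format is headered tab-separated text with columns `chrom`,
#' `pos` (1-based), `ancestral`, `d1`, `d2` and optionally `d_out`: the
#' derived-allele counts (0/1/2) in the population-1 individual, the
#' population-2 individual and the outgroup individual.
#'
#' @param path file path.
#' @return [read_site_table()] returns a data frame of site records.
#' @export
read_site_table <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  need <- c("chrom", "pos", "ancestral", "d1", "d2")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("site table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab
}

#' @param records a site-record data frame.
#' @rdname read_site_table
#' @export
write_site_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Shared validation + block assignment for the tally functions. Returns the
# records with a `.block` column, plus a drop-reason summary.
.prepare_records <- function(records, block_size) {
  need <- c("chrom", "pos", "d1", "d2")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(records) == 0L) stop("empty site-record input")
  stopifnot(block_size > 0)
  # sorted by (chrom, pos): positions nondecreasing within a chromosome and
  # no chromosome appearing in more than one run
  runs <- rle(as.character(records$chrom))$values
  if (anyDuplicated(runs) > 0L) {
    stop("records are not sorted: chromosome ",
         runs[anyDuplicated(runs)], " appears in more than one run")
  }
  pos_ok <- tapply(records$pos, factor(records$chrom, levels = runs),
                   function(p) !is.unsorted(p))
  if (!all(pos_ok)) {
    stop("records are not sorted by position within chromosome ",
         names(pos_ok)[!pos_ok][1L])
  }

  drop <- rep(NA_character_, nrow(records))
  if ("valid" %in% names(records)) {
    drop[!is.na(records$valid) & !records$valid] <- "failed_upstream_filter"
  }
  bad_d <- function(d) is.na(d) | d < 0 | d > 2 | d != floor(d)
  sel <- is.na(drop) & (bad_d(records$d1) | bad_d(records$d2))
  drop[sel] <- "derived_count_out_of_range"

  keep <- is.na(drop)
  reasons <- table(drop[!keep])
  rec <- records[keep, , drop = FALSE]
  rec$.block <- paste0(rec$chrom, ":",
                       floor((rec$pos - 1) / block_size))
  list(records = rec,
       drop_reasons = stats::setNames(as.integer(reasons), names(reasons)),
       n_input = nrow(records))
}

.tally <- function(rec) {
  m <- matrix(0, 3, 3)
  tab <- table(factor(rec$d1, levels = 0:2), factor(rec$d2, levels = 0:2))
  m[] <- as.numeric(tab)
  config_counts(m)
}

#' Tally site records into per-block configuration counts
#'
#' Counts valid sites by sample configuration within contiguous genomic
#' blocks. `m_tot` counts every valid site, monomorphic sites included;
#' invalid records (upstream filter failures, out-of-range derived counts)
#' are excluded from `m_tot` and reported in the `drop_reasons` attribute.
#'
#' @param records site-record data frame (see [read_site_table()]), sorted by
#'   chromosome and position.
#' @param block_size physical block span in base pairs (default 5 Mb); blocks
#'   are `[1, block_size]`, `(block_size, 2 block_size]`, ... per chromosome.
#' @return a [blocked_counts] object with attributes `drop_reasons` (named
#'   integer vector) and `n_input`.
#' @export
tally_counts <- function(records, block_size = 5e6) {
  prep <- .prepare_records(records, block_size)
  rec <- prep$records
  if (nrow(rec) == 0L) stop("no valid sites to tally")
  blocks <- lapply(split(rec, factor(rec$.block, levels = unique(rec$.block))),
                   .tally)
  out <- blocked_counts(blocks)
  attr(out, "drop_reasons") <- prep$drop_reasons
  attr(out, "n_input") <- prep$n_input
  out
}

#' Tally outgroup-ascertained configuration counts
#'
#' Restricts the tally to sites whose derived allele is present in the
#' outgroup individual — the ascertainment that guarantees the variant
#' predates the population split. `m_tot` is the number of ascertained
#' sites.
#'
#' @inheritParams tally_counts
#' @param rule `"any"` (default): at least one derived allele copy in the
#'   outgroup (`d_out >= 1`); `"fixed"`: both copies derived (`d_out == 2`).
#' @return a [blocked_counts] object of ascertained counts (attributes as in
#'   [tally_counts()]).
#' @export
ascertained_tally <- function(records, rule = c("any", "fixed"),
                              block_size = 5e6) {
  rule <- match.arg(rule)
  if (!"d_out" %in% names(records)) {
    stop("outgroup ascertainment requires a `d_out` column")
  }
  prep <- .prepare_records(records, block_size)
  rec <- prep$records
  bad <- is.na(rec$d_out) | rec$d_out < 0 | rec$d_out > 2
  prep$drop_reasons <- c(prep$drop_reasons,
                         if (any(bad)) c(outgroup_count_invalid = sum(bad)))
  rec <- rec[!bad, , drop = FALSE]
  rec <- rec[if (rule == "any") rec$d_out >= 1 else rec$d_out == 2, ,
             drop = FALSE]
  if (nrow(rec) == 0L) stop("no ascertained sites under rule '", rule, "'")
  blocks <- lapply(split(rec, factor(rec$.block, levels = unique(rec$.block))),
                   .tally)
  out <- blocked_counts(blocks)
  attr(out, "drop_reasons") <- prep$drop_reasons
  attr(out, "n_input") <- prep$n_input
  out
}

#' Read site records from a VCF file
#'
#' Convenience wrapper producing the same record stream as
#' [read_site_table()] from a (plain-text) VCF with diploid genotype calls
#' and the ancestral allele in the `AA` INFO tag. Sites without an `AA` tag
#' or with non-diploid calls are emitted as invalid records (so the tally
#' reports them in its drop summary). Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @param sample1,sample2 sample column names for the two in-group
#'   individuals.
#' @param outgroup optional sample column name of the outgroup individual.
#' @return site-record data frame with columns `chrom`, `pos`, `ancestral`,
#'   `d1`, `d2`, `valid` and, if requested, `d_out`.
#' @export
read_sites_vcf <- function(path, sample1, sample2, outgroup = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_sites_vcf() requires the `vcfR` package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  for (s in c(sample1, sample2, outgroup)) {
    if (!s %in% colnames(gt)) stop("sample not found in VCF: ", s)
  }
  aa <- sub("^.*AA=([^;]*).*$", "\\1", vcfR::getINFO(v))
  aa[!grepl("AA=", vcfR::getINFO(v))] <- NA_character_

  resolve <- function(code, ref, alt) {
    # numeric GT codes to alleles; non-diploid or missing -> NA
    if (is.na(code)) return(NA_character_)
    parts <- strsplit(code, "[/|]")[[1L]]
    if (length(parts) != 2L || any(parts == ".")) return(NA_character_)
    alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1L]])
    i <- as.integer(parts) + 1L
    if (any(is.na(i)) || any(i > length(alleles))) return(NA_character_)
    paste(alleles[i], collapse = "/")
  }
  n <- nrow(fix)
  d1 <- d2 <- d_out <- rep(NA_integer_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(aa[i])) next
    g1 <- resolve(gt[i, sample1], fix[i, "REF"], fix[i, "ALT"])
    g2 <- resolve(gt[i, sample2], fix[i, "REF"], fix[i, "ALT"])
    if (is.na(g1) || is.na(g2)) next
    pol <- polarize_site(g1, g2, aa[i])
    if (!pol$valid) next
    d1[i] <- pol$d1
    d2[i] <- pol$d2
    valid[i] <- TRUE
    if (!is.null(outgroup)) {
      go <- resolve(gt[i, outgroup], fix[i, "REF"], fix[i, "ALT"])
      if (is.na(go)) {
        valid[i] <- FALSE
        next
      }
      oa <- strsplit(go, "/", fixed = TRUE)[[1L]]
      der <- setdiff(unique(c(strsplit(g1, "/")[[1L]],
                              strsplit(g2, "/")[[1L]], oa)), aa[i])
      if (length(der) > 1L) {  # tri-allelic once the outgroup is included
        valid[i] <- FALSE
        d1[i] <- d2[i] <- NA_integer_
        next
      }
      d_out[i] <- sum(oa != aa[i])
    }
  }
  out <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    ancestral = aa, d1 = d1, d2 = d2, valid = valid,
                    stringsAsFactors = FALSE)
  if (!is.null(outgroup)) out$d_out <- d_out
  out
}
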