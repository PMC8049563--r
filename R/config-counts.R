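#' Sample-configuration site counts for the 2+2 sampling design
#'
#' A `config_counts` object holds the joint site-frequency spectrum of two
#' diploid individuals: the number of sites `m[i][j]` at which the individual
#' from population 1 carries `i` derived alleles and the individual from
#' population 2 carries `j` (`i`, `j` in 0, 1, 2), together with the total
#' number of investigated sites `m_tot` (monomorphic sites included).
#'
#' Counts may be real-valued: expected (rather than sampled) counts produced
#' by [simulate_counts()] are fractional and are accepted by all estimators.
#'
#' @param m 3x3 numeric matrix of site counts; rows index the derived-allele
#'   count (0, 1, 2) in the population-1 individual, columns in the
#'   population-2 individual. A named vector with names `"m00"` ... `"m22"`
#'   is also accepted (missing cells default to 0).
#' @param m_tot total number of sites examined. Defaults to `sum(m)`. If
#'   larger than `sum(m)`, the difference is attributed to the monomorphic
#'   ancestral cell `m[0,0]` (convenient when only polymorphic cells are
#'   recorded).
#' @return An object of class `config_counts` with elements `m` (3x3 matrix
#'   with dimnames `"0","1","2"`) and `m_tot`.
#' @examples
#' cc <- config_counts(c(m11 = 400, m21 = 400, m12 = 400), m_tot = 1e6)
#' cc$m["1", "1"]
#' @export
config_counts <- function(m, m_tot = NULL) {
  if (is.vector(m) && !is.null(names(m))) {
    v <- m
    m <- matrix(0, 3, 3)
    for (nm in names(v)) {
      ij <- .parse_cell(nm)
      m[ij[1] + 1L, ij[2] + 1L] <- v[[nm]]
    }
  }
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) {
    stop("`m` must be a 3x3 matrix of site counts")
  }
  mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0)) {
    stop("site counts must be nonnegative and non-missing")
  }
  if (is.null(m_tot)) m_tot <- sum(m)
  if (m_tot < sum(m) - 1e-8 * max(1, sum(m))) {
    stop("`m_tot` (", m_tot, ") is smaller than the sum of the cells (",
         sum(m), ")")
  }
  # absorb unaccounted (monomorphic) sites into the 0,0 cell
  m[1L, 1L] <- m[1L, 1L] + max(0, m_tot - sum(m))
  dimnames(m) <- list(pop1 = c("0", "1", "2"), pop2 = c("0", "1", "2"))
  structure(list(m = m, m_tot = m_tot), class = "config_counts")
}

.parse_cell <- function(nm) {
  ok <- grepl("^m[0-2][0-2]\\*?$", nm)
  if (!ok) stop("unrecognized configuration-cell name: ", nm)
  c(as.integer(substr(nm, 2, 2)), as.integer(substr(nm, 3, 3)))
}

#' @export
print.config_counts <- function(x, ...) {
  cat("2+2 sample-configuration counts (m_tot =",
      format(x$m_tot, big.mark = ","), "sites)\n")
  print(x$m)
  invisible(x)
}

#' Swap the two populations of a counts object
#'
#' Transposes the configuration matrix, i.e. relabels population 1 as
#' population 2. Used by the symmetry checks of the estimators.
#'
#' @param x a [config_counts] object.
#' @return a [config_counts] object with `m` transposed.
#' @export
transpose_counts <- function(x) {
  stopifnot(inherits(x, "config_counts"))
  config_counts(t(x$m), m_tot = x$m_tot)
}

#' Sum several counts objects cellwise
#'
#' @param ... [config_counts] objects (or a single list of them).
#' @return a [config_counts] object with summed cells and `m_tot`.
#' @export
sum_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "config_counts")) xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "config_counts")))
  m <- Reduce(`+`, lapply(xs, `[[`, "m"))
  config_counts(m, m_tot = sum(vapply(xs, `[[`, 0, "m_tot")))
}

#' Per-block configuration counts for the block jackknife
#'
#' @param blocks named list of [config_counts], one per contiguous genomic
#'   block, in genome order.
#' @return an object of class `blocked_counts` with elements `blocks` and
#'   `total` (the cellwise sum).
#' @seealso [tally_counts()], [block_jackknife()]
#' @export
blocked_counts <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1L,
            all(vapply(blocks, inherits, TRUE, "config_counts")))
  if (is.null(names(blocks))) names(blocks) <- as.character(seq_along(blocks))
  structure(list(blocks = blocks, total = sum_counts(blocks)),
            class = "blocked_counts")
}

#' @export
print.blocked_counts <- function(x, ...) {
  cat("blocked_counts:", length(x$blocks), "blocks, total m_tot =",
      format(x$total$m_tot, big.mark = ","), "\n")
  invisible(x)
}

#' Read / write configuration counts as key=value text
#'
#' The on-disk format is one `key=value` pair per line with keys `m00` ...
#' `m22` and `m_tot`; `#` starts a comment. Cells absent from the file
#' default to zero (the remainder `m_tot - sum` is treated as `m00`).
#'
#' @param path file path.
#' @return [read_config_counts()] returns a [config_counts] object.
#' @export
read_config_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed line in counts file: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  if (anyNA(vals)) stop("non-numeric value in counts file")
  names(vals) <- keys
  m_tot <- if ("m_tot" %in% keys) vals[["m_tot"]] else NULL
  vals <- vals[keys != "m_tot"]
  config_counts(vals, m_tot = m_tot)
}

#' @param x a [config_counts] object.
#' @rdname read_config_counts
#' @export
write_config_counts <- function(x, path) {
  stopifnot(inherits(x, "config_counts"))
  cells <- c(outer(0:2, 0:2, function(i, j) sprintf("m%d%d", i, j)))
  vals <- c(outer(0:2, 0:2, Vectorize(function(i, j) x$m[i + 1, j + 1])))
  writeLines(c(sprintf("%s=%.10g", cells, vals),
               sprintf("m_tot=%.10g", x$m_tot)), path)
  invisible(path)
}

#' Sample-configuration probabilities
#'
#' The nine per-site configuration probabilities `p[i][j]` of the forward
#' model. The two monomorphic-looking corners (all-ancestral `p[0,0]` and
#' all-derived `p[2,2]`) are not separated by the four-leaf infinite-sites
#' model and are carried as the single lump `p00_p22 = 1 - sum(polymorphic)`;
#' in the matrix representation those two cells are `NA`.
#'
#' @param p 3x3 numeric matrix of the seven polymorphic probabilities (cells
#'   `[0,0]` and `[2,2]` ignored), or a named vector `p10`, `p01`, ... .
#' @return object of class `config_probs`: elements `p` (3x3 matrix, `NA` in
#'   the lumped corners), `p00_p22` (the lump) and `poly_total`.
#' @export
config_probs <- function(p) {
  if (is.vector(p) && !is.null(names(p))) {
    v <- p
    p <- matrix(0, 3, 3)
    for (nm in names(v)) {
      ij <- .parse_cell(sub("^p", "m", nm))
      p[ij[1] + 1L, ij[2] + 1L] <- v[[nm]]
    }
  }
  p <- as.matrix(p)
  stopifnot(all(dim(p) == c(3L, 3L)))
  mode(p) <- "numeric"
  p[1L, 1L] <- NA_real_
  p[3L, 3L] <- NA_real_
  poly <- sum(p, na.rm = TRUE)
  neg <- which(!is.na(p) & p < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf("negative configuration probability p[%d,%d] = %.3g",
                 neg[1L, 1L] - 1L, neg[1L, 2L] - 1L,
                 p[neg[1L, 1L], neg[1L, 2L]]))
  }
  if (poly > 1) stop("polymorphic probabilities sum to ", poly, " > 1")
  dimnames(p) <- list(pop1 = c("0", "1", "2"), pop2 = c("0", "1", "2"))
  structure(list(p = p, p00_p22 = 1 - poly, poly_total = poly),
            class = "config_probs")
}

#' @export
print.config_probs <- function(x, ...) {
  cat("2+2 configuration probabilities (p00 + p22 lump =",
      format(x$p00_p22), ")\n")
  print(x$p)
  invisible(x)
}

#' Expected counts at a given number of sites
#'
#' Multiplies configuration probabilities by `m_tot`, placing the monomorphic
#' lump in the `[0,0]` cell. The inverse, up to the lump split, of
#' `counts$m / counts$m_tot`.
#'
#' @param probs a [config_probs] object.
#' @param m_tot number of sites.
#' @return a [config_counts] object with real-valued cells.
#' @export
expected_counts <- function(probs, m_tot) {
  stopifnot(inherits(probs, "config_probs"), m_tot > 0)
  m <- probs$p * m_tot
  m[1L, 1L] <- probs$p00_p22 * m_tot
  m[3L, 3L] <- 0
  config_counts(m, m_tot = m_tot)
}
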