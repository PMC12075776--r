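# Downstream ecology on externally produced tables: RPKM normalization of
# competitive read-recruitment counts, subcluster abundance sums,
# ANI-threshold species clustering, genome quality scores, and
# abundance-environment rank correlation.

#' RPKM normalization of a recruitment count matrix
#'
#' Reads Per Kilobase (of genome) per Million (of recruited read base
#' pairs): \code{RPKM[g, s] = counts[g, s] / (length_g / 1e3) /
#' (recruited_bp_s / 1e6)}. The denominator is the per-sample total base
#' pairs of recruited (mapped) reads; supply total sample base pairs instead
#' if that convention is wanted.
#'
#' @param counts genomes x samples matrix of mapped-read counts
#'   (non-negative), with row and column names.
#' @param genome_lengths_bp named vector of genome lengths (bp, > 0) for
#'   every row of \code{counts}.
#' @param recruited_bp named vector of per-sample recruited base pairs; must
#'   be positive wherever a sample has any counts.
#' @return An object of class \code{"rpkm_table"}: the \code{rpkm} matrix
#'   plus a per-genome \code{genome_summary} (median and quartiles across
#'   samples) ranked by median RPKM.
#' @export
compute_rpkm <- function(counts, genome_lengths_bp, recruited_bp) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs genome rownames and sample colnames", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  glen <- genome_lengths_bp[rownames(counts)]
  if (anyNA(glen)) stop("missing genome length(s)", call. = FALSE)
  if (any(glen <= 0)) stop("genome lengths must be positive", call. = FALSE)
  rb <- recruited_bp[colnames(counts)]
  if (anyNA(rb)) stop("missing recruited_bp for some sample(s)", call. = FALSE)
  bad <- rb <= 0 & colSums(counts) > 0
  if (any(bad))
    stop("recruited_bp must be positive where counts are nonzero: ",
         paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  denom <- outer(as.numeric(glen) / 1e3, as.numeric(rb) / 1e6)
  rpkm <- counts / denom
  rpkm[counts == 0] <- 0  # covers 0-count samples with recruited_bp = 0
  qs <- t(apply(rpkm, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75)))
  gs <- data.frame(genome = rownames(counts), q25 = qs[, 1L],
                   median = qs[, 2L], q75 = qs[, 3L], row.names = NULL)
  gs <- gs[order(-gs$median), , drop = FALSE]
  gs$rank <- seq_len(nrow(gs))
  rownames(gs) <- NULL
  structure(list(rpkm = rpkm, genome_lengths_bp = glen,
                 recruited_bp = rb, genome_summary = gs),
            class = "rpkm_table")
}

#' @export
print.rpkm_table <- function(x, digits = 4, ...) {
  cat(sprintf("RPKM table: %d genomes x %d samples\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  cat("Top recruiting genomes (by median RPKM):\n")
  print(utils::head(x$genome_summary, 5L), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Summed RPKM per subcluster and sample
#'
#' Sums the RPKM of all member genomes of each subcluster within each
#' sample; genomes missing from the membership map are excluded with a
#' warning. The per-subcluster median across samples is also reported.
#'
#' @param x an \code{"rpkm_table"} (or a bare RPKM matrix with dimnames).
#' @param membership named vector mapping genome id to subcluster id.
#' @return A list with the subcluster x sample \code{sums} matrix and
#'   per-subcluster \code{medians} across samples.
#' @export
subcluster_abundance <- function(x, membership) {
  rpkm <- if (inherits(x, "rpkm_table")) x$rpkm else as.matrix(x)
  if (length(membership) == 0L) stop("empty membership map", call. = FALSE)
  known <- rownames(rpkm) %in% names(membership)
  if (!any(known)) stop("no genome in the membership map", call. = FALSE)
  if (!all(known))
    warning("excluding ", sum(!known), " genome(s) absent from membership: ",
            paste(utils::head(rownames(rpkm)[!known], 5L), collapse = ", "),
            call. = FALSE)
  rpkm <- rpkm[known, , drop = FALSE]
  grp <- factor(membership[rownames(rpkm)])
  sums <- rowsum(rpkm, grp)
  list(sums = sums,
       medians = apply(sums, 1L, stats::median))
}

#' ANI-threshold species clustering
#'
#' Symmetrizes a (possibly asymmetric) pairwise average nucleotide identity
#' matrix, links genome pairs whose symmetrized ANI meets the threshold, and
#' takes connected components as species-level clusters (single linkage,
#' mirroring the ~95% bacterial species boundary). Within-cluster minimum
#' and median ANI and between-cluster minimum and maximum ANI are reported;
#' the threshold constrains edges, not all within-cluster pairs.
#'
#' @param ani square matrix of pairwise ANI percentages (0-100) with
#'   matching dimnames; diagonal 100. NA off-diagonal entries (e.g. pairs a
#'   tool did not report) are treated as below any threshold.
#' @param threshold edge threshold in percent (default 95, the conventional
#'   species boundary).
#' @param symmetrize \code{"mean"} (default) or \code{"min"} of the two
#'   directed values.
#' @return An object of class \code{"ani_clusters"}: \code{clusters} (named
#'   membership vector), \code{within} (per-cluster size, min and median
#'   ANI), \code{between} (min/max between-cluster ANI) and the symmetrized
#'   matrix.
#' @export
ani_clusters <- function(ani, threshold = 95, symmetrize = c("mean", "min")) {
  symmetrize <- match.arg(symmetrize)
  ani <- as.matrix(ani)
  if (nrow(ani) != ncol(ani)) stop("ANI matrix must be square", call. = FALSE)
  if (is.null(rownames(ani))) rownames(ani) <- colnames(ani)
  if (is.null(rownames(ani)))
    rownames(ani) <- colnames(ani) <- paste0("g", seq_len(nrow(ani)))
  if (!identical(rownames(ani), colnames(ani)))
    ani <- ani[, rownames(ani), drop = FALSE]
  vals <- ani[is.finite(ani)]
  if (any(vals < 0 | vals > 100))
    stop("ANI values must lie in [0, 100]", call. = FALSE)
  if (any(abs(diag(ani) - 100) > 1e-6))
    stop("ANI diagonal must be 100 (self identity)", call. = FALSE)
  sym <- if (symmetrize == "mean") {
    m <- (ani + t(ani)) / 2
    # keep the available direction when only one is reported
    m[is.na(m)] <- pmax(ani, t(ani), na.rm = TRUE)[is.na(m)]
    m
  } else pmin(ani, t(ani))
  adj <- !is.na(sym) & sym >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- stats::setNames(as.integer(comp), rownames(ani))
  within <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    members <- names(clusters)[clusters == cl]
    if (length(members) > 1L) {
      block <- sym[members, members]
      offdiag <- block[lower.tri(block)]
      data.frame(cluster = cl, n = length(members),
                 min_ani = min(offdiag), median_ani = stats::median(offdiag))
    } else {
      data.frame(cluster = cl, n = 1L, min_ani = NA_real_,
                 median_ani = NA_real_)
    }
  }))
  between_vals <- sym[outer(clusters, clusters, "!=") &
                        lower.tri(sym, diag = FALSE)]
  between_vals <- between_vals[!is.na(between_vals)]
  between <- if (length(between_vals))
    c(min = min(between_vals), max = max(between_vals))
  else c(min = NA_real_, max = NA_real_)
  structure(list(clusters = clusters, within = within, between = between,
                 threshold = threshold, symmetrize = symmetrize,
                 ani = sym), class = "ani_clusters")
}

#' @export
print.ani_clusters <- function(x, digits = 4, ...) {
  cat(sprintf("ANI clustering at %.4g%% (%s symmetrization): %d genomes, %d cluster(s)\n",
              x$threshold, x$symmetrize, length(x$clusters),
              length(unique(x$clusters))))
  print(x$within, digits = digits, row.names = FALSE)
  if (!is.na(x$between[["min"]]))
    cat(sprintf("  between-cluster ANI: min %.*g%%, max %.*g%%\n",
                digits, x$between[["min"]], digits, x$between[["max"]]))
  invisible(x)
}

#' Genome quality score
#'
#' Quality = completeness - 5 x contamination (the dereplication convention
#' for picking cluster representatives).
#'
#' @param completeness percent in [0, 100], vectorized.
#' @param contamination percent >= 0, vectorized.
#' @return Numeric score(s).
#' @export
genome_quality <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must lie in [0, 100]", call. = FALSE)
  if (any(contamination < 0))
    stop("contamination must be >= 0", call. = FALSE)
  completeness - 5 * contamination
}

#' Rank correlation between subcluster abundance and an environmental variable
#'
#' Spearman rank correlation per subcluster between summed abundance and a
#' per-sample environmental value (e.g. temperature); samples with missing
#' values are excluded pairwise. Constant abundance (or environment) leaves
#' the correlation undefined; it is returned as NA with \code{defined =
#' FALSE} rather than raising.
#'
#' @param sums subcluster x sample abundance matrix (e.g.
#'   \code{subcluster_abundance(...)$sums}).
#' @param env named per-sample environmental values covering the columns of
#'   \code{sums}.
#' @return A data.frame with \code{subcluster}, \code{rho}, \code{n},
#'   \code{defined}.
#' @export
env_abundance_correlation <- function(sums, env) {
  sums <- as.matrix(sums)
  e <- if (!is.null(names(env))) env[colnames(sums)] else env
  if (length(e) != ncol(sums))
    stop("`env` must cover every sample column", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(sums)), function(i) {
    a <- sums[i, ]
    ok <- is.finite(a) & is.finite(e)
    if (sum(ok) < 3L)
      stop("fewer than 3 complete abundance/environment pairs for subcluster ",
           rownames(sums)[i], call. = FALSE)
    rho <- if (stats::sd(a[ok]) == 0 || stats::sd(e[ok]) == 0) NA_real_
           else suppressWarnings(
             stats::cor(a[ok], e[ok], method = "spearman"))
    data.frame(subcluster = rownames(sums)[i], rho = rho, n = sum(ok),
               defined = !is.na(rho))
  }))
  rownames(out) <- NULL
  out
}

#' Read a pairwise ANI matrix
#'
#' Accepts either a square labelled CSV/TSV (first column = genome ids,
#' header = genome ids) or fastANI-style long format with three columns
#' (query, reference, ANI; extra columns ignored). Missing pairs in long
#' format become NA; the diagonal is set to 100.
#'
#' @param path path to the file.
#' @return A square numeric matrix with dimnames.
#' @export
read_ani <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           stringsAsFactors = FALSE)
  is_long <- ncol(raw) >= 3L && ncol(raw) <= 5L &&
    suppressWarnings(all(is.na(as.numeric(raw[[2L]])))) &&
    !suppressWarnings(anyNA(as.numeric(raw[-1L, 3L])))
  if (is_long) {
    # fastANI-style: query, reference, ANI (+ optional fragment columns)
    if (suppressWarnings(is.na(as.numeric(raw[1L, 3L]))))
      raw <- raw[-1L, , drop = FALSE]  # drop header row
    genomes <- sort(unique(c(raw[[1L]], raw[[2L]])))
    m <- matrix(NA_real_, length(genomes), length(genomes),
                dimnames = list(genomes, genomes))
    m[cbind(match(raw[[1L]], genomes), match(raw[[2L]], genomes))] <-
      as.numeric(raw[[3L]])
    diag(m) <- 100
    m
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
  }
}
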