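# T-RFLP fingerprint computations: in-silico terminal restriction
# fragment prediction from labelled 16S amplicons, single-linkage
# fragment clustering at a bp threshold, per-replicate peak
# normalization, and replicate summaries.

#' Restriction enzyme description
#'
#' @param name Enzyme name.
#' @param site Recognition site (A/C/G/T, length >= 4).
#' @param cut_offset Cut position within the site, bases after the
#'   site's first base (MspI C^CGG: offset 1).
#' @return A list of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme()  # MspI
#' @export
restriction_enzyme <- function(name = "MspI", site = "CCGG",
                               cut_offset = 1) {
  site <- toupper(site)
  stopifnot(nchar(site) >= 4, grepl("^[ACGT]+$", site),
            cut_offset >= 0, cut_offset < nchar(site))
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' Predict terminal restriction fragment lengths in silico
#'
#' For each sequence, anchors the labelled (forward) primer's 5' end --
#' at the first exact-or-degenerate primer match when the primer is
#' given (IUPAC codes in the primer are expanded; template bases are
#' matched literally, so N in the template never matches), otherwise at
#' position 1 -- then scans downstream for the first occurrence of the
#' enzyme's recognition site.  The T-RF length counts from the anchored
#' 5' end through the last base before the cut:
#' `(site_start - anchor) + cut_offset`.  Sequences without a site
#' report the full remaining length, flagged `"undigested"`; sequences
#' where the primer cannot be found are skipped with a warning.
#'
#' @param sequences A `Biostrings::DNAStringSet`, named character vector
#'   of sequences, or path to a FASTA file.
#' @param primer Labelled forward primer sequence (IUPAC degeneracy
#'   allowed), or `NULL` to anchor every sequence at position 1.
#' @param enzyme A [restriction_enzyme()].
#' @return data.frame with columns `id`, `trf_bp`, `flag` (`""` or
#'   `"undigested"`).
#' @examples
#' seqs <- c(x = paste0(strrep("A", 161), "CCGG", strrep("T", 50)))
#' insilico_digest(seqs)$trf_bp  # 162
#' @export
insilico_digest <- function(sequences, primer = NULL,
                            enzyme = restriction_enzyme()) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    names(sequences) <- paste0("seq", seq_along(sequences))

  out <- lapply(seq_along(sequences), function(i) {
    seq_i <- sequences[[i]]
    id <- names(sequences)[i]
    anchor <- 1L
    if (!is.null(primer)) {
      m <- Biostrings::matchPattern(Biostrings::DNAString(toupper(primer)),
                                    seq_i, fixed = "subject")
      if (length(m) == 0) {
        warning("primer not found in '", id, "'; record skipped")
        return(NULL)
      }
      anchor <- Biostrings::start(m)[1]
    }
    remaining <- Biostrings::subseq(seq_i, start = anchor)
    # literal site scan: IUPAC letters or N in the template never match
    hit <- regexpr(enzyme$site, as.character(remaining), fixed = TRUE)
    if (hit == -1) {
      data.frame(id = id, trf_bp = length(remaining), flag = "undigested",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = id, trf_bp = as.integer(hit) - 1L + enzyme$cut_offset,
                 flag = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Construct a T-RFLP peak table
#'
#' @param replicate_id Replicate identifiers.
#' @param size_bp Fragment sizes, bp (fractional capillary sizes
#'   allowed; > 0).
#' @param height Peak heights, arbitrary units (>= 0).
#' @return data.frame of class `peak_table`.
#' @export
peak_table <- function(replicate_id, size_bp, height) {
  stopifnot(all(size_bp > 0), all(height >= 0))
  structure(data.frame(replicate_id = as.character(replicate_id),
                       size_bp = as.numeric(size_bp),
                       height = as.numeric(height),
                       stringsAsFactors = FALSE),
            class = c("peak_table", "data.frame"))
}

#' Read a peak table from delimited text
#'
#' Expects columns `replicate_id`, `size_bp`, `height`; comma or tab
#' auto-detected.
#'
#' @param path File path.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  peak_table(d$replicate_id, d$size_bp, d$height)
}

#' Cluster fragment sizes by single linkage at a bp threshold
#'
#' Deterministic 1D single-linkage clustering: sizes are sorted and a
#' new cluster starts wherever the gap between consecutive sizes exceeds
#' the threshold.  Consecutive gaps at or below the threshold chain into
#' one cluster, so members of a cluster can span more than one
#' threshold.  Centroid = height-weighted mean size, reported to 0.1 bp.
#'
#' @param table A [peak_table()] (any data.frame with `size_bp` and
#'   `height`).
#' @param threshold Clustering threshold, bp (default 2).
#' @return The table with added integer column `cluster` plus attribute
#'   `centroids` (named numeric vector, cluster -> centroid bp).  Empty
#'   input returns an empty table.
#' @examples
#' pt <- peak_table("a", c(159, 160.4, 163), c(1, 1, 1))
#' attr(cluster_fragments(pt), "centroids")  # two clusters
#' @export
cluster_fragments <- function(table, threshold = 2) {
  stopifnot(threshold > 0)
  if (nrow(table) == 0) {
    table$cluster <- integer(0)
    attr(table, "centroids") <- numeric(0)
    return(table)
  }
  ord <- order(table$size_bp)
  sizes <- table$size_bp[ord]
  breaks <- c(0, cumsum(diff(sizes) > threshold))
  cl <- integer(nrow(table))
  cl[ord] <- breaks + 1L
  table$cluster <- cl
  cent <- vapply(split(seq_len(nrow(table)), cl), function(idx) {
    ht <- table$height[idx]
    if (sum(ht) > 0) round(stats::weighted.mean(table$size_bp[idx], ht), 1)
    else round(mean(table$size_bp[idx]), 1)
  }, numeric(1))
  attr(table, "centroids") <- cent
  table
}

#' Normalize peak heights to relative abundances per replicate
#'
#' Within each replicate, heights are divided by the replicate's total
#' height, so relative heights sum to 1 per replicate.
#'
#' @param table A [peak_table()].
#' @return The table with `height` replaced by relative abundance.
#' @export
normalize_fingerprint <- function(table) {
  totals <- tapply(table$height, table$replicate_id, sum)
  zero <- names(totals)[totals <= 0]
  if (length(zero))
    stop("replicate(s) with no positive peak height: ",
         paste(zero, collapse = ", "))
  table$height <- table$height / as.numeric(totals[table$replicate_id])
  table
}

#' Summarize T-RF relative abundances across replicates
#'
#' Normalizes each replicate, clusters fragment sizes jointly across all
#' replicates at the given threshold, and reports the mean and sample
#' standard deviation of the per-replicate relative abundance of each
#' cluster.  A cluster absent from a replicate counts as relative
#' abundance 0 there.
#'
#' @param tables List of [peak_table()]s (>= 2 replicates in total), or
#'   a single combined table with distinct `replicate_id`s.
#' @param threshold Clustering threshold, bp.
#' @return data.frame with `cluster`, `centroid_bp`, `mean_abundance`,
#'   `sd_abundance`, `n_replicates`.
#' @examples
#' reps <- lapply(1:3, function(i)
#'   peak_table(paste0("r", i), c(159, 502), c(40, 60)))
#' summarize_replicates(reps)
#' @export
summarize_replicates <- function(tables, threshold = 2) {
  if (is.data.frame(tables)) tables <- list(tables)
  combined <- do.call(rbind, lapply(tables, function(t)
    t[, c("replicate_id", "size_bp", "height")]))
  reps <- unique(combined$replicate_id)
  if (length(reps) < 2) stop("need >= 2 replicates, got ", length(reps))
  combined <- normalize_fingerprint(combined)
  combined <- cluster_fragments(combined, threshold)
  cent <- attr(combined, "centroids")
  res <- lapply(sort(unique(combined$cluster)), function(cl) {
    sub <- combined[combined$cluster == cl, ]
    ab <- vapply(reps, function(r)
      sum(sub$height[sub$replicate_id == r]), numeric(1))
    data.frame(cluster = cl, centroid_bp = cent[[as.character(cl)]],
               mean_abundance = mean(ab),
               sd_abundance = stats::sd(ab),
               n_replicates = length(reps))
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
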