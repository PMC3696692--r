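# Gly/Pro content statistics over TMD regions of aligned sequence sets.
#
# Glycine and proline are helix breakers; their abundance in the
# transmembrane helices of an ABC exporter is a sequence-level proxy for
# TMD flexibility.

.AA_OK <- c(LETTERS[LETTERS %in% c("A","C","D","E","F","G","H","I","K","L","M",
                                   "N","P","Q","R","S","T","V","W","Y",
                                   "B","Z","X","J","U","O")], "-")

#' Count Gly and Pro in a region of one gapped sequence
#'
#' Counts are over non-gap characters only; ambiguity codes (B, Z, X, ...)
#' contribute to `n_residues` but never to the Gly/Pro counts.
#' Case-insensitive.
#'
#' @param row a gapped sequence string.
#' @param span 0-based half-open column interval `c(start, end)`; defaults
#'   to the full sequence.
#' @return list with `n_gly`, `n_pro`, `n_residues`.
#' @export
count_glypro <- function(row, span = NULL) {
  row <- toupper(row)
  if (is.null(span)) span <- c(0L, nchar(row))
  if (span[1] < 0 || span[2] > nchar(row) || span[1] > span[2])
    stop("span outside [0, ", nchar(row), ")")
  seg <- if (span[2] > span[1]) substr(row, span[1] + 1L, span[2]) else ""
  ch <- strsplit(seg, "")[[1]]
  bad <- setdiff(unique(ch), .AA_OK)
  if (length(bad)) stop("non-amino-acid character(s): ", paste(bad, collapse = ", "))
  ch <- ch[ch != "-"]
  list(n_gly = sum(ch == "G"), n_pro = sum(ch == "P"), n_residues = length(ch))
}

#' Per-sequence Gly/Pro composition of an alignment region
#'
#' @param block an `AlignmentBlock`.
#' @param region name of a region span in `block$region_spans`.
#' @return a `CompositionSummary`: list with `counts` (data.frame `seq_id`,
#'   `n_gly`, `n_pro`, `n_residues`, ordered by `seq_id`), `joint` (a table
#'   over `(n_gly, n_pro)` whose total equals the number of sequences), and
#'   `marginals` (means and quartiles of the two counts).
#' @export
summarize_composition <- function(block, region = "full") {
  if (!region %in% names(block$region_spans))
    stop("unknown region '", region, "'")
  span <- block$region_spans[[region]]
  ord <- order(block$ids)
  counts <- do.call(rbind, lapply(ord, function(i) {
    ct <- count_glypro(block$rows[i], span)
    data.frame(seq_id = block$ids[i], n_gly = ct$n_gly, n_pro = ct$n_pro,
               n_residues = ct$n_residues)
  }))
  rownames(counts) <- NULL
  joint <- table(gly = counts$n_gly, pro = counts$n_pro)
  marg <- list(
    mean_gly = mean(counts$n_gly), mean_pro = mean(counts$n_pro),
    q_gly = quantile(counts$n_gly, c(.25, .5, .75)),
    q_pro = quantile(counts$n_pro, c(.25, .5, .75)))
  structure(list(region = region, counts = counts, joint = joint,
                 marginals = marg), class = "CompositionSummary")
}

#' @export
print.CompositionSummary <- function(x, ...) {
  cat(sprintf("CompositionSummary '%s': %d sequences, mean Gly %.2f, mean Pro %.2f\n",
              x$region, nrow(x$counts), x$marginals$mean_gly, x$marginals$mean_pro))
  invisible(x)
}

#' Compare Gly/Pro content between two sequence groups
#'
#' Differences of mean per-sequence Gly and Pro counts (group A minus
#' group B) with seeded percentile bootstrap confidence intervals.
#'
#' @param summary_a,summary_b `CompositionSummary` objects.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed (no global random state is consumed).
#' @param conf confidence level.
#' @return data.frame with one row per residue (`gly`, `pro`): observed
#'   mean difference and CI bounds.
#' @export
compare_groups <- function(summary_a, summary_b, n_boot = 10000, seed = 1,
                           conf = 0.95) {
  a <- summary_a$counts; b <- summary_b$counts
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  boot_one <- function(xa, xb) {
    diffs <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i)
        mean(sample(xa, replace = TRUE)) - mean(sample(xb, replace = TRUE)),
        numeric(1))
    })
    c(mean(xa) - mean(xb), quantile(diffs, qs))
  }
  g <- boot_one(a$n_gly, b$n_gly)
  p <- boot_one(a$n_pro, b$n_pro)
  out <- data.frame(residue = c("gly", "pro"),
                    diff_mean = c(g[1], p[1]),
                    ci_lo = c(g[2], p[2]), ci_hi = c(g[3], p[3]))
  attr(out, "n_boot") <- n_boot
  attr(out, "conf") <- conf
  out
}
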