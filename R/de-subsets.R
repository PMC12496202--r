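## Intersectional classification of differential-expression results from
## the three pairwise comparisons MvF (male vs female), IvF (intersex vs
## female) and MvI (male vs intersex).

.subset_labels <- c("full_recovery", "male_independent",
                    "partial_recovery", "mvf_only",
                    "not_male_upregulated")

#' Parameters for the differential-expression table simulator
#'
#' Describes a transcript universe with planted intersectional structure:
#' four male-upregulated subsets (defaults follow the sizes
#' 632/172/89/1092 of the full-recovery, male-independent,
#' partial-recovery and MvF-only subsets), a female-upregulated block,
#' and a null remainder.
#'
#' @param n_genes Universe size (default 20000).
#' @param subset_sizes Named integer vector with entries
#'   \code{full_recovery}, \code{male_independent},
#'   \code{partial_recovery}, \code{mvf_only}.
#' @param n_female_up Number of female-upregulated transcripts
#'   (significantly down in MvF and IvF).
#' @param effect_size Mean |log2 fold change| of true effects (> 0).
#' @param fdr_threshold Significance threshold on adjusted p (default
#'   0.05).
#' @param spurious_nulls If \code{TRUE}, null transcripts draw adjusted p
#'   uniformly on (0, 1) and may be spuriously significant; the default
#'   \code{FALSE} draws them uniformly above the threshold, so the tables
#'   state exactly the planted decision pattern.
#' @param seed Integer seed.
#' @return A \code{"de_sim_params"} object.
#' @export
de_sim_params <- function(n_genes = 20000,
                          subset_sizes = c(full_recovery = 632,
                                           male_independent = 172,
                                           partial_recovery = 89,
                                           mvf_only = 1092),
                          n_female_up = 2000,
                          effect_size = 4,
                          fdr_threshold = 0.05,
                          spurious_nulls = FALSE,
                          seed = NULL) {
  need <- c("full_recovery", "male_independent", "partial_recovery",
            "mvf_only")
  if (!all(need %in% names(subset_sizes))) {
    stop("`subset_sizes` must be named with: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  subset_sizes <- subset_sizes[need]
  if (any(subset_sizes < 0) || n_female_up < 0) {
    stop("sizes must be non-negative", call. = FALSE)
  }
  if (sum(subset_sizes) + n_female_up > n_genes) {
    stop("planted sizes exceed `n_genes`", call. = FALSE)
  }
  .check_scalar(effect_size, "effect_size", positive = TRUE)
  .check_scalar(fdr_threshold, "fdr_threshold")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("`fdr_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), subset_sizes = subset_sizes,
         n_female_up = as.integer(n_female_up),
         effect_size = effect_size, fdr_threshold = fdr_threshold,
         spurious_nulls = isTRUE(spurious_nulls),
         seed = .check_seed(seed)),
    class = "de_sim_params")
}

#' Simulate the three differential-expression comparison tables
#'
#' Generates MvF, IvF and MvI result tables (columns
#' \code{transcript_id}, \code{log2fc}, \code{padj}) over a shared
#' transcript universe in which each planted subset satisfies exactly its
#' defining significance/sign pattern: significant comparisons draw
#' adjusted p uniformly below a tenth of the threshold with fold changes
#' of the planted sign around \code{effect_size}; non-significant
#' comparisons draw adjusted p above the threshold with small,
#' sign-symmetric fold changes. The modelling of the underlying
#' count data and multiplicity correction is out of scope - the tables
#' emulate the exported end product of a DE pipeline.
#'
#' @param params A [de_sim_params()] object.
#' @return A list with data frames \code{mvf}, \code{ivf}, \code{mvi} and
#'   a \code{truth} data frame (\code{transcript_id}, \code{label}).
#' @export
simulate_de_tables <- function(params = de_sim_params()) {
  stopifnot(inherits(params, "de_sim_params"))
  n <- params$n_genes
  thr <- params$fdr_threshold
  sizes <- params$subset_sizes
  ids <- sprintf("TX%06d", seq_len(n))

  label <- rep("null", n)
  pos <- 1L
  for (lab in names(sizes)) {
    k <- sizes[[lab]]
    if (k > 0) label[pos:(pos + k - 1L)] <- lab
    pos <- pos + k
  }
  if (params$n_female_up > 0) {
    label[pos:(pos + params$n_female_up - 1L)] <- "female_up"
  }

  ## per-comparison planted status for each label: "up", "down" or "ns"
  patterns <- list(
    full_recovery    = c(mvf = "up",   ivf = "up",   mvi = "ns"),
    male_independent = c(mvf = "up",   ivf = "ns",   mvi = "up"),
    partial_recovery = c(mvf = "up",   ivf = "up",   mvi = "up"),
    mvf_only         = c(mvf = "up",   ivf = "ns",   mvi = "ns"),
    female_up        = c(mvf = "down", ivf = "down", mvi = "ns"),
    null             = c(mvf = "ns",   ivf = "ns",   mvi = "ns"))

  .with_seed(params$seed, {
    make_table <- function(comparison) {
      status <- vapply(label, function(l) patterns[[l]][[comparison]], "")
      lfc <- numeric(n)
      padj <- numeric(n)
      sig <- status != "ns"
      nsig <- sum(sig)
      eff <- abs(stats::rnorm(nsig, mean = params$effect_size,
                              sd = params$effect_size / 8))
      lfc[sig] <- ifelse(status[sig] == "up", eff, -eff)
      padj[sig] <- stats::runif(nsig, 0, thr / 10)
      lfc[!sig] <- stats::rnorm(n - nsig, sd = 0.2)
      if (params$spurious_nulls) {
        is_null <- !sig & label == "null"
        padj[!sig & !is_null] <- stats::runif(sum(!sig & !is_null), thr, 1)
        padj[is_null] <- stats::runif(sum(is_null), 0, 1)
      } else {
        padj[!sig] <- stats::runif(n - nsig, thr, 1)
      }
      data.frame(transcript_id = ids, log2fc = lfc, padj = padj,
                 stringsAsFactors = FALSE)
    }
    list(mvf = make_table("mvf"), ivf = make_table("ivf"),
         mvi = make_table("mvi"),
         truth = data.frame(transcript_id = ids, label = label,
                            stringsAsFactors = FALSE))
  })
}

.validate_de_table <- function(tab, name) {
  need <- c("transcript_id", "log2fc", "padj")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    stop(sprintf("`%s` must be a data frame with columns %s", name,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(tab$transcript_id)) {
    stop(sprintf("duplicate transcript ids in `%s`", name), call. = FALSE)
  }
  ok <- is.na(tab$padj) | (tab$padj >= 0 & tab$padj <= 1)
  if (!all(ok)) {
    stop(sprintf("`%s` has adjusted p-values outside [0, 1]", name),
         call. = FALSE)
  }
  invisible(tab)
}

#' Classify transcripts into intersectional male-upregulation subsets
#'
#' Assigns every transcript present in all three comparison tables to one
#' of five mutually exclusive labels based on its significance/sign
#' pattern at the FDR threshold (significant means adjusted p strictly
#' below the threshold; "up" additionally requires log2 fold change > 0,
#' i.e. higher expression in the left-hand group of the comparison):
#'
#' \itemize{
#'   \item \code{full_recovery}: up in MvF and IvF, not significant in
#'     MvI - male-level expression fully recovered in the intersex mutant.
#'   \item \code{male_independent}: up in MvF and MvI, not significant in
#'     IvF - male-biased expression untouched by the mutation.
#'   \item \code{partial_recovery}: up in all three comparisons.
#'   \item \code{mvf_only}: up in MvF, not significant in IvF or MvI.
#'   \item \code{not_male_upregulated}: everything else.
#' }
#'
#' The four male-up labels partition the set of transcripts up in MvF.
#' With \code{direction = "down"} the same logic applies to negative fold
#' changes (female-side analysis). Missing adjusted p-values are treated
#' as non-significant; transcripts absent from any table are dropped with
#' a recorded count.
#'
#' @param mvf,ivf,mvi Data frames with columns \code{transcript_id},
#'   \code{log2fc}, \code{padj}.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @param direction "up" (default) or "down".
#' @return A \code{"subset_assignment"} data frame: \code{transcript_id},
#'   \code{label} (factor), per-comparison significance and sign columns.
#'   Attributes: \code{counts} (per-label table), \code{n_dropped},
#'   \code{n_missing_padj}.
#' @export
classify_subsets <- function(mvf, ivf, mvi, fdr_threshold = 0.05,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  .check_scalar(fdr_threshold, "fdr_threshold")
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    stop("`fdr_threshold` must lie in (0, 1)", call. = FALSE)
  }
  .validate_de_table(mvf, "mvf")
  .validate_de_table(ivf, "ivf")
  .validate_de_table(mvi, "mvi")

  shared <- Reduce(intersect, list(mvf$transcript_id, ivf$transcript_id,
                                   mvi$transcript_id))
  n_dropped <- length(unique(c(mvf$transcript_id, ivf$transcript_id,
                               mvi$transcript_id))) - length(shared)
  if (n_dropped > 0) {
    warning(sprintf(
      "%d transcript(s) absent from at least one table were excluded",
      n_dropped))
  }

  align <- function(tab) tab[match(shared, tab$transcript_id), ]
  a <- align(mvf); b <- align(ivf); c_ <- align(mvi)
  n_missing_padj <- sum(is.na(a$padj)) + sum(is.na(b$padj)) +
    sum(is.na(c_$padj))

  sig <- function(tab) !is.na(tab$padj) & tab$padj < fdr_threshold
  dirsel <- function(tab) {
    if (direction == "up") tab$log2fc > 0 else tab$log2fc < 0
  }
  up_mvf <- sig(a) & dirsel(a)
  sig_ivf <- sig(b)
  sig_mvi <- sig(c_)

  ## Within the MvF-up gate the four subset definitions reduce to the
  ## 2x2 significance pattern of (IvF, MvI): requiring "up" (rather than
  ## merely significant) in the supporting comparison changes nothing for
  ## sign-concordant data, and splitting by significance keeps the four
  ## labels an exhaustive partition of {up in MvF} even for discordant
  ## sign patterns.
  label <- rep("not_male_upregulated", length(shared))
  label[up_mvf & sig_ivf & !sig_mvi] <- "full_recovery"
  label[up_mvf & !sig_ivf & sig_mvi] <- "male_independent"
  label[up_mvf & sig_ivf & sig_mvi] <- "partial_recovery"
  label[up_mvf & !sig_ivf & !sig_mvi] <- "mvf_only"

  out <- data.frame(
    transcript_id = shared,
    label = factor(label, levels = .subset_labels),
    mvf_sig = sig(a), mvf_log2fc = a$log2fc,
    ivf_sig = sig_ivf, ivf_log2fc = b$log2fc,
    mvi_sig = sig_mvi, mvi_log2fc = c_$log2fc,
    stringsAsFactors = FALSE)
  class(out) <- c("subset_assignment", "data.frame")
  attr(out, "counts") <- table(out$label)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_missing_padj") <- n_missing_padj
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "direction") <- direction
  out
}

#' @export
print.subset_assignment <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("<subset_assignment> %d transcripts (FDR < %g, direction %s)\n",
              nrow(x), attr(x, "fdr_threshold"), attr(x, "direction")))
  for (l in names(cnt)) cat(sprintf("  %-22s %d\n", l, cnt[[l]]))
  invisible(x)
}

#' Overlap between two transcript lists
#'
#' Exact set intersection and differences between two id sets, e.g. the
#' male-upregulated lists of two mosquito strains; reports the shared
#' fraction of the union (Jaccard index).
#'
#' @param list_a,list_b Character vectors of transcript ids (deduplicated
#'   internally).
#' @return A list: \code{shared}, \code{only_a}, \code{only_b} (counts)
#'   and \code{shared_fraction_of_union}.
#' @export
#' @examples
#' overlap_de_lists(c("a", "b", "c"), c("b", "c", "d"))
overlap_de_lists <- function(list_a, list_b) {
  a <- unique(as.character(list_a))
  b <- unique(as.character(list_b))
  shared <- length(intersect(a, b))
  union_n <- length(union(a, b))
  list(shared = shared,
       only_a = length(a) - shared,
       only_b = length(b) - shared,
       shared_fraction_of_union = if (union_n > 0) shared / union_n else NaN)
}

#' Read / write differential-expression tables
#'
#' Tab-separated text with header
#' \code{transcript_id<TAB>log2fc<TAB>padj}; [write_de_table()] appends a
#' \code{subset_label} column when given a [classify_subsets()] result.
#'
#' @param path File path.
#' @param tab Data frame to write.
#' @return \code{read_de_table}: a validated data frame.
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .validate_de_table(tab[, intersect(names(tab),
                                     c("transcript_id", "log2fc", "padj"))],
                     path)
  tab
}

#' @rdname read_de_table
#' @export
write_de_table <- function(tab, path) {
  if (inherits(tab, "subset_assignment")) {
    out <- data.frame(transcript_id = tab$transcript_id,
                      log2fc = tab$mvf_log2fc,
                      padj = NA_real_,
                      subset_label = as.character(tab$label))
  } else {
    out <- tab
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
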