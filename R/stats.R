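#' Aggregate events into error rates
#'
#' Divides event counts by the total number of analyzable sequenced bases per
#' group. \code{totals} gives the denominator per template (and strand class);
#' deletions consume denominator bases, insertions do not, so the denominator
#' is the count of analyzable reference positions covered by accepted
#' molecules. Indel events are counted once per collapsed event.
#'
#' @param events event data.frame (as produced by the calling pipeline, with
#'   a \code{template} column added by the caller; if absent, a single
#'   template \code{"template"} is assumed).
#' @param totals data.frame with columns \code{template} and \code{n_bases},
#'   covering every template contributing events, or a single number used for
#'   all templates.
#' @param by extra grouping columns of \code{events} (e.g. \code{"strand"},
#'   \code{"type"}, \code{"rnap_pair"}).
#' @return data.frame with the grouping columns, \code{n_events},
#'   \code{n_bases} and \code{rate}. Groups present in \code{totals} but
#'   without events get rate 0 only for the grouping values observed
#'   elsewhere; use \code{\link{rateSummary}} for template averaging.
#' @examples
#' ev <- data.frame(template = "t1", strand = "first", type = "substitution")
#' computeRates(ev[rep(1, 5), ], totals = 1e5, by = "type")
#' @export
computeRates <- function(events, totals, by = c("strand", "type")) {
  if (!nrow(events)) stop("no events; build the table from counts directly")
  if (!"template" %in% names(events)) events$template <- "template"
  if (is.numeric(totals))
    totals <- data.frame(template = unique(events$template), n_bases = totals)
  missing <- setdiff(unique(events$template), totals$template)
  if (length(missing))
    stop("totals must cover every template: missing ",
         paste(missing, collapse = ", "))
  if (any(totals$n_bases <= 0)) stop("zero total bases for a group")
  keys <- c("template", by)
  cnt <- aggregate(list(n_events = rep(1L, nrow(events))),
                   events[keys], FUN = sum)
  out <- merge(cnt, totals[c("template", "n_bases")], by = "template")
  out$rate <- out$n_events / out$n_bases
  out[do.call(order, out[keys]), , drop = FALSE]
}

#' Mean and standard deviation of rates across templates
#'
#' Reduces a per-template rate table to its mean and SD per remaining group,
#' the form reported for each enzyme/condition. Templates with zero events in
#' a group are counted as rate 0 (supply \code{templates} so absent
#' template/group combinations contribute zeros).
#'
#' @param rates output of \code{\link{computeRates}}.
#' @param by grouping columns to keep (default: all except template/counts).
#' @param templates character vector of all template labels (default: those
#'   present).
#' @return data.frame with grouping columns, \code{mean_rate}, \code{sd_rate}
#'   and \code{n_templates}.
#' @export
rateSummary <- function(rates, by = setdiff(names(rates),
                                            c("template", "n_events",
                                              "n_bases", "rate")),
                        templates = unique(rates$template)) {
  full <- expand.grid(c(list(template = templates),
                        lapply(rates[by], unique)),
                      stringsAsFactors = FALSE)
  m <- merge(full, rates, by = c("template", by), all.x = TRUE)
  m$rate[is.na(m$rate)] <- 0
  agg <- aggregate(list(mean_rate = m$rate), m[by], FUN = mean)
  agg$sd_rate <- aggregate(list(sd = m$rate), m[by], FUN = sd)$sd
  agg$n_templates <- length(templates)
  agg
}

#' Percentage composition of error types
#'
#' Splits total errors into substitution/deletion/insertion percentages per
#' group (rows sum to 100 up to rounding).
#'
#' @param events event data.frame.
#' @param by grouping columns (default \code{"strand"}).
#' @return data.frame with grouping columns, \code{type}, \code{n_events}
#'   and \code{percent}.
#' @export
errorTypePercentages <- function(events, by = "strand") {
  cnt <- aggregate(list(n_events = rep(1L, nrow(events))),
                   events[c(by, "type")], FUN = sum)
  tot <- aggregate(list(total = cnt$n_events), cnt[, by, drop = FALSE],
                   FUN = sum)
  out <- merge(cnt, tot, by = by)
  out$percent <- 100 * out$n_events / out$total
  out$total <- NULL
  out
}

#' Relative fold change of a substitution rate
#'
#' \code{(M - S) / S}, where \code{M} is the rate on modified-base RNA and
#' \code{S} the rate on unmodified RNA: 0 means no change, -1 complete
#' suppression. Undefined (NA) when \code{S} is 0.
#'
#' @param M,S rates (vectorised).
#' @return numeric fold changes; NA with a warning where \code{S = 0}.
#' @examples
#' foldChange(2e-4, 1e-4)  # 1
#' foldChange(0, 1e-4)     # -1
#' @export
foldChange <- function(M, S) {
  out <- ifelse(S > 0, (M - S) / S, NA_real_)
  if (any(S <= 0))
    warning("fold change undefined where the unmodified rate is 0; ",
            "reported as NA")
  out
}

#' Fold-change table over substitution subtypes
#'
#' Joins per-subtype rates from a modified and an unmodified condition and
#' computes \code{(M - S)/S} per subtype.
#'
#' @param ratesMod,ratesUnmod data.frames with columns \code{subtype} and
#'   \code{rate}.
#' @return data.frame with \code{subtype}, \code{M}, \code{S}, \code{fold}.
#' @export
foldChangeTable <- function(ratesMod, ratesUnmod) {
  m <- merge(ratesMod[c("subtype", "rate")], ratesUnmod[c("subtype", "rate")],
             by = "subtype", all = TRUE, suffixes = c("_M", "_S"))
  m$rate_M[is.na(m$rate_M)] <- 0
  m$rate_S[is.na(m$rate_S)] <- 0
  data.frame(subtype = m$subtype, M = m$rate_M, S = m$rate_S,
             fold = suppressWarnings(foldChange(m$rate_M, m$rate_S)),
             stringsAsFactors = FALSE)
}

#' Compare per-template rates between two conditions
#'
#' Two-sample two-sided Welch t-test on per-template rates, with Bonferroni
#' adjustment of the significance level: significance is declared iff
#' \code{p < alpha / nComparisons}.
#'
#' @param ratesA,ratesB numeric vectors of per-template rates (>= 2 each).
#' @param nComparisons number of simultaneous comparisons (Bonferroni).
#' @param alpha family significance level (default 0.05).
#' @return list with \code{statistic}, \code{p.value}, \code{alphaAdjusted}
#'   and \code{significant}.
#' @export
compareConditions <- function(ratesA, ratesB, nComparisons = 1L,
                              alpha = 0.05) {
  if (length(ratesA) < 2L || length(ratesB) < 2L)
    stop("at least 2 replicates per condition are required")
  tt <- t.test(ratesA, ratesB, var.equal = FALSE,
               alternative = "two.sided")
  adj <- alpha / nComparisons
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       alphaAdjusted = adj, significant = tt$p.value < adj)
}

#' Indel size distribution
#'
#' Percentage of collapsed indel events of sizes 1, 2, 3 and >= 4, separately
#' for deletions and insertions, per group. Rows sum to 100 up to rounding;
#' groups with no events of a type are flagged empty.
#'
#' @param events event data.frame (collapsed indel events; substitutions are
#'   ignored).
#' @param by grouping columns (default \code{"strand"}).
#' @return data.frame with grouping columns, \code{type}, size-bin
#'   percentages \code{s1}, \code{s2}, \code{s3}, \code{s4plus},
#'   \code{n_events} and \code{empty}.
#' @export
indelSizeDistribution <- function(events, by = "strand") {
  ind <- events[events$type %in% c("deletion", "insertion"), , drop = FALSE]
  out <- list()
  grid <- if (nrow(ind)) unique(ind[, by, drop = FALSE])
          else data.frame()
  for (g in seq_len(max(1L, nrow(grid)))) {
    sel <- if (nrow(grid))
      Reduce(`&`, lapply(by, function(cn) ind[[cn]] == grid[g, cn]))
    else rep(TRUE, nrow(ind))
    for (tp in c("deletion", "insertion")) {
      sz <- ind$length[sel & ind$type == tp]
      n <- length(sz)
      bins <- c(sum(sz == 1L), sum(sz == 2L), sum(sz == 3L), sum(sz >= 4L))
      pct <- if (n > 0L) 100 * bins / n else rep(0, 4L)
      row <- if (nrow(grid)) grid[g, , drop = FALSE] else
        data.frame(row.names = 1L)
      row$type <- tp
      row$s1 <- pct[1L]; row$s2 <- pct[2L]; row$s3 <- pct[3L]
      row$s4plus <- pct[4L]
      row$n_events <- n
      row$empty <- n == 0L
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank error hotspots
#'
#' Ranks reference positions by event count, separately per error type, and
#' returns the top positions with counts and reference context. Ties are
#' broken by ascending position.
#'
#' @param events event data.frame from a single template.
#' @param amplicon the reference \code{\linkS4class{Amplicon}}.
#' @param topK positions to return per type (default 3).
#' @param contextWidth half-width of the reported reference context.
#' @return named list (substitution/deletion/insertion) of data.frames with
#'   \code{ref_pos}, \code{count}, \code{context}; empty when a type has no
#'   events.
#' @export
rankHotspots <- function(events, amplicon, topK = 3L, contextWidth = 5L) {
  refCh <- strsplit(amplicon@sequence, "", fixed = TRUE)[[1L]]
  out <- list()
  for (tp in c("substitution", "deletion", "insertion")) {
    ev <- events[events$type == tp, , drop = FALSE]
    if (!nrow(ev)) {
      out[[tp]] <- data.frame(ref_pos = integer(), count = integer(),
                              context = character(), stringsAsFactors = FALSE)
      next
    }
    t <- table(ev$ref_pos)
    df <- data.frame(ref_pos = as.integer(names(t)),
                     count = as.integer(t), stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$ref_pos), , drop = FALSE]
    df <- head(df, topK)
    df$context <- vapply(df$ref_pos, function(p) {
      lo <- max(1L, p + 1L - contextWidth)
      hi <- min(length(refCh), p + 1L + contextWidth)
      paste(refCh[lo:hi], collapse = "")
    }, "")
    rownames(df) <- NULL
    out[[tp]] <- df
  }
  out
}

#' Sequence-context profile of substitution events
#'
#' Base-frequency matrix of the reference bases flanking substitution events,
#' reported in the RNA alphabet (RNA-sense): rows are offsets -W..-1 and
#' +1..+W relative to the event position, columns are A/C/G/U fractions.
#' Events whose window extends beyond the reference are excluded and counted.
#'
#' @param events substitution events (pre-filter to one subtype for a
#'   per-subtype logo matrix).
#' @param amplicon the reference \code{\linkS4class{Amplicon}}.
#' @param window half-width W (default 3).
#' @return list with \code{freq} (2W x 4 matrix, rows summing to 1),
#'   \code{n_events} and \code{n_excluded}.
#' @export
contextProfile <- function(events, amplicon, window = 3L) {
  ev <- events[events$type == "substitution", , drop = FALSE]
  refCh <- strsplit(amplicon@sequence, "", fixed = TRUE)[[1L]]
  L <- length(refCh)
  offsets <- c(-(window:1), 1:window)
  ok <- ev$ref_pos - window >= 0L & ev$ref_pos + window <= L - 1L
  used <- ev[ok, , drop = FALSE]
  freq <- matrix(0, nrow = 2L * window, ncol = 4L,
                 dimnames = list(sprintf("%+d", offsets),
                                 c("A", "C", "G", "U")))
  if (nrow(used)) {
    for (k in seq_along(offsets)) {
      b <- refCh[used$ref_pos + offsets[k] + 1L]
      t <- table(factor(chartr("T", "U", b), levels = c("A", "C", "G", "U")))
      freq[k, ] <- as.numeric(t) / nrow(used)
    }
  }
  list(freq = freq, n_events = nrow(used), n_excluded = sum(!ok))
}
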