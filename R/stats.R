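#' Between-group dispersion of TF DNA binding: the variability index
#'
#' For a transcription factor's ChIP-Seq signal grouped by the four
#' transcriptional-output classes, compute each group's deciles (0.1–0.9,
#' linear-interpolation quantiles), and at each decile the sample standard
#' deviation across groups normalized by the across-group mean (a coefficient
#' of variation per decile, since raw dispersion grows with signal level).
#' The variability index is the sum of the nine normalized dispersions: 0
#' when all groups bind equally, large when binding strength separates the
#' groups. The index is invariant to global positive scaling and to group
#' relabeling.
#'
#' @param data Tibble with a signal column and a grouping column.
#' @param value,group Column names (strings) of signal and group (defaults
#'   `"value"`, `"group"`).
#' @param deciles Probabilities at which group quantiles are taken.
#' @param tf_name Optional label carried into the result.
#' @param pooled If `TRUE`, deciles are taken on the pooled data and each
#'   group's quantiles are computed at those pooled values' probabilities —
#'   retained as a switch; the default (per-group deciles) is the primary
#'   definition.
#' @return Object of class `tf_variability`: `tf_name`, `per_decile` tibble
#'   (`decile`, one column per group, `sd`, `mean`, `dispersion`),
#'   `variability_index` (NA-flagged when any decile mean is 0), `n_per_group`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
variability_index <- function(data, value = "value", group = "group",
                              deciles = seq(0.1, 0.9, by = 0.1),
                              tf_name = NULL, pooled = FALSE) {
  if (!all(c(value, group) %in% names(data))) {
    abort(paste0("data needs columns '", value, "' and '", group, "'"))
  }
  v <- data[[value]]
  g <- as.character(data[[group]])
  if (anyNA(v)) abort("signal values must not be missing")
  sizes <- table(g)
  if (length(sizes) < 2) abort("need at least 2 non-empty groups")
  if (any(sizes < 10)) {
    abort(paste0("group(s) with fewer than 10 values: ",
                 paste(names(sizes)[sizes < 10], collapse = ", ")))
  }
  groups <- sort(names(sizes))
  qmat <- vapply(groups, function(gr) {
    quantile(v[g == gr], probs = deciles, type = 7, names = FALSE)
  }, numeric(length(deciles)))
  if (pooled) {
    # quantiles still per group but anchored at pooled decile values' ECDF
    pooled_q <- quantile(v, probs = deciles, type = 7, names = FALSE)
    qmat <- vapply(groups, function(gr) {
      probs <- stats::ecdf(v)(pooled_q)
      quantile(v[g == gr], probs = pmin(pmax(probs, 0), 1), type = 7,
               names = FALSE)
    }, numeric(length(deciles)))
  }
  s_d <- apply(qmat, 1, sd)
  m_d <- apply(qmat, 1, mean)
  disp <- ifelse(m_d == 0, NA_real_, s_d / m_d)
  per_decile <- tibble(decile = deciles)
  for (i in seq_along(groups)) per_decile[[groups[i]]] <- qmat[, i]
  per_decile$sd <- s_d
  per_decile$mean <- m_d
  per_decile$dispersion <- disp
  structure(
    list(
      tf_name = tf_name %||% "TF",
      per_decile = per_decile,
      variability_index = if (anyNA(disp)) NA_real_ else sum(disp),
      n_per_group = setNames(as.integer(sizes[groups]), groups)
    ),
    class = "tf_variability"
  )
}

#' @export
print.tf_variability <- function(x, ...) {
  cat(sprintf("TF DNA binding variability index for %s: %s\n", x$tf_name,
              format(x$variability_index, digits = 4)))
  cat(sprintf("  groups (n): %s\n",
              paste(names(x$n_per_group), x$n_per_group, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @rdname variability_index
#' @param x,object A `tf_variability`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tf_variability <- function(x, ...) x$per_decile

#' @rdname variability_index
#' @exportS3Method generics::glance
glance.tf_variability <- function(x, ...) {
  tibble(tf_name = x$tf_name, variability_index = x$variability_index,
         n_groups = length(x$n_per_group), n_total = sum(x$n_per_group))
}

#' @rdname variability_index
#' @exportS3Method ggplot2::autoplot
autoplot.tf_variability <- function(object, ...) {
  ggplot2::ggplot(object$per_decile,
                  ggplot2::aes(factor(.data$decile), .data$dispersion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "decile", y = "between-group SD / mean",
      title = sprintf("%s — variability index %.3g", object$tf_name,
                      object$variability_index)
    ) +
    ggplot2::theme_minimal()
}

#' Kruskal-Wallis comparison with a compact letter display
#'
#' Omnibus Kruskal-Wallis test across groups, followed by pairwise Dunn tests
#' (standard-normal z statistics on mean ranks with a tie correction) with
#' Benjamini-Hochberg adjustment, summarized as a compact letter display:
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param data Tibble with signal and group columns.
#' @param value,group Column names (strings), defaults `"value"`, `"group"`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `circout_letters`: `p.value` (omnibus), `letters`
#'   tibble (`group`, `n`, `median`, `letters`), `pairwise` tibble of Dunn
#'   z/p/p.adj per pair, `alpha`.
#' @export
kruskal_letters <- function(data, value = "value", group = "group",
                            alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 values")

  if (length(unique(v)) == 1) {
    # fully tied data: nothing distinguishes any group
    omni <- 1
    pw <- tibble(group1 = character(), group2 = character(),
                 z = numeric(), p.value = numeric(), p.adj = numeric())
    sig <- matrix(FALSE, nlevels(g), nlevels(g),
                  dimnames = list(levels(g), levels(g)))
  } else {
    omni <- kruskal.test(v, g)$p.value
    pw <- dunn_pairwise(v, g)
    sig <- matrix(FALSE, nlevels(g), nlevels(g),
                  dimnames = list(levels(g), levels(g)))
    for (i in seq_len(nrow(pw))) {
      # pairs only differ when the omnibus test itself rejects
      s <- omni < alpha && pw$p.adj[i] < alpha
      sig[pw$group1[i], pw$group2[i]] <- s
      sig[pw$group2[i], pw$group1[i]] <- s
    }
  }
  letters_tb <- tibble(
    group = levels(g),
    n = as.integer(table(g)),
    median = as.numeric(tapply(v, g, median)),
    letters = letter_display(sig)
  )
  structure(list(p.value = omni, letters = letters_tb, pairwise = pw,
                 alpha = alpha),
            class = "circout_letters")
}

#' @export
print.circout_letters <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis p = %.4g (alpha = %g)\n", x$p.value, x$alpha))
  print(x$letters)
  invisible(x)
}

# Dunn's z tests on mean ranks with tie correction; two-sided p, BH adjusted
dunn_pairwise <- function(v, g) {
  r <- rank(v)
  N <- length(v)
  rbar <- tapply(r, g, mean)
  n <- table(g)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[p[1]]] + 1 / n[[p[2]]]))
    (rbar[[p[1]]] - rbar[[p[2]]]) / se
  })
  pv <- 2 * pnorm(-abs(z))
  tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = as.numeric(z),
         p.value = as.numeric(pv),
         p.adj = p.adjust(pv, method = "BH"))
}

# insert-and-absorb compact letter display from a logical "significantly
# different" matrix (groups in rownames order)
letter_display <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))   # start: one letter containing every group
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (idx in seq_len(nrow(pairs))) {
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    touched <- which(vapply(cols, function(cl) cl[i] && cl[j], logical(1)))
    for (t in touched) {
      a <- cols[[t]]; b <- cols[[t]]
      a[i] <- FALSE; b[j] <- FALSE
      cols[[t]] <- a
      cols[[length(cols) + 1]] <- b
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (p in seq_along(cols)) {
      for (q in seq_along(cols)) {
        if (p != q && keep[p] && keep[q] &&
            all(cols[[p]] <= cols[[q]]) && any(cols[[q]] & !cols[[p]])) {
          keep[p] <- FALSE
        }
      }
    }
    # also drop exact duplicates
    sig_str <- vapply(cols, function(cl) paste(cl, collapse = ""), character(1))
    keep <- keep & !duplicated(sig_str)
    cols <- cols[keep]
  }
  lab <- letters[seq_along(cols)]
  vapply(seq_len(k), function(i) {
    paste(lab[vapply(cols, function(cl) cl[i], logical(1))], collapse = "")
  }, character(1))
}

#' Two-way ANOVA on rhythm extremes
#'
#' Compares rhythm amplitudes between output classes by a group x extremum
#' (max vs min) two-way ANOVA on the per-replicate extremes from
#' [minmax_amplitude()]: a significant interaction (or a group effect on the
#' max-min contrast) means amplitudes differ between groups.
#'
#' @param data Tibble with columns `group`, `extremum` (`"max"`/`"min"`) and
#'   `value`; long format, one row per replicate x extremum.
#' @return Tibble `term`, `df`, `sumsq`, `statistic`, `p.value` for group,
#'   extremum, interaction and residuals. Degenerate zero-variance input
#'   returns p = 1 for all effects.
#' @export
amplitude_anova <- function(data) {
  need <- c("group", "extremum", "value")
  if (!all(need %in% names(data))) abort("data needs columns group, extremum, value")
  cells <- table(data$group, data$extremum)
  if (any(cells < 1)) abort("every group x extremum cell needs at least one observation")
  if (stats::var(data$value) == 0 || is.na(stats::var(data$value))) {
    return(tibble(
      term = c("group", "extremum", "group:extremum", "Residuals"),
      df = NA_integer_, sumsq = 0, statistic = c(0, 0, 0, NA),
      p.value = c(1, 1, 1, NA)
    ))
  }
  fit <- aov(value ~ group * extremum,
             data = mutate(data, group = factor(.data$group),
                           extremum = factor(.data$extremum)))
  tab <- summary(fit)[[1]]
  tibble(
    term = trimws(rownames(tab)),
    df = tab[["Df"]],
    sumsq = tab[["Sum Sq"]],
    statistic = tab[["F value"]],
    p.value = tab[["Pr(>F)"]]
  )
}

#' Chi-square test of genomic-location composition between classes
#'
#' Thin wrapper comparing the distribution of peak location categories
#' (TSS / gene body / extended promoter / intergenic) across output classes.
#'
#' @param classified Output of [classify_peaks()] with `location` and
#'   `output_class`.
#' @return `htest` from [stats::chisq.test()] on the class x location table.
#' @export
location_chisq <- function(classified) {
  keep <- classified[!is.na(classified$output_class), , drop = FALSE]
  stats::chisq.test(table(droplevels(keep$output_class),
                          droplevels(keep$location)))
}

#' Core clock gene symbols shipped with the package
#'
#' The editable exclusion list used for "non-core-clock" re-analyses of the
#' variability index (canonical symbols for Rev-erb alpha/beta and Ror gamma
#' are Nr1d1/Nr1d2/Rorc).
#'
#' @param path Optional path to an alternative one-symbol-per-line file.
#' @return Character vector of gene symbols.
#' @export
core_clock_genes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "core_clock_genes.txt",
                                package = "circout")
  x <- readr::read_lines(path)
  x <- trimws(x[!grepl("^\\s*(#|$)", x)])
  x
}
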