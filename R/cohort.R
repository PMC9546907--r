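#' Paired Student t-test
#'
#' Two-tailed paired t on matched samples: with `d = x - y`,
#' `t = mean(d) / (sd(d) / sqrt(n))` (n-1 denominator in `sd`), and `p` the
#' two-tailed tail probability of Student's t with `n - 1` degrees of
#' freedom. When every difference is zero, `t = 0` and `p = 1`; a zero
#' spread with a nonzero mean difference gives `p = 0` with a warning.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, matched by subject.
#' @param paired set `FALSE` for the two-sample (Welch) form, offered for
#'   comparison with the default paired analysis.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y, paired = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("sample-size error: need n >= 2 pairs")
  if (!paired) {
    ht <- stats::t.test(x, y)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1L, p = 1))
    warning("degenerate variance: all differences identical and nonzero")
    return(list(t = sign(m) * Inf, df = n - 1L, p = 0))
  }
  tt <- m / (s / sqrt(n))
  list(t = tt, df = n - 1L, p = 2 * stats::pt(-abs(tt), df = n - 1L))
}

check_cohort <- function(table) {
  need <- c("subject_id", "session", "technique", "angle_deg")
  if (!all(need %in% names(table)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  if (!all(table$session %in% c("pre", "post")))
    stop("session must be 'pre' or 'post'")
  if (anyDuplicated(table[, c("subject_id", "session", "technique")]))
    stop("duplicate (subject, session, technique) rows in cohort table")
  if (!all(is.finite(table$angle_deg))) stop("angles must be finite")
  invisible(table)
}

#' Per-technique pre/post summary of a cohort table
#'
#' Means and standard deviations (n-1 denominator) per technique and
#' session, the pre mean-to-STD ratio (a consistency indicator across
#' subjects; `Inf` when the STD is zero), and the paired two-tailed p value
#' for the pre vs post difference. Subjects missing one session are included
#' in the means but excluded from the paired test, with a log note.
#'
#' @param table a cohort table (see [simulate_cohort()], [read_cohort_csv()]).
#' @param paired use the paired test (default) or the two-sample form.
#' @return data frame, one row per technique: `technique`, `pre_mean`,
#'   `pre_std`, `post_mean`, `post_std`, `mean_to_std_ratio_pre`,
#'   `p_pre_vs_post`.
#' @export
summarize_cohort <- function(table, paired = TRUE) {
  check_cohort(table)
  techs <- unique(table$technique)
  rows <- lapply(techs, function(tech) {
    sub <- table[table$technique == tech, , drop = FALSE]
    pre <- sub[sub$session == "pre", , drop = FALSE]
    post <- sub[sub$session == "post", , drop = FALSE]
    if (nrow(pre) == 0L || nrow(post) == 0L)
      stop("missing-data error: technique ", tech, " lacks a session")
    common <- intersect(pre$subject_id, post$subject_id)
    dropped <- length(unique(sub$subject_id)) - length(common)
    if (dropped > 0L)
      message(sprintf("summarize_cohort: %d subject(s) missing one session excluded from the %s paired test",
                      dropped, tech))
    ht <- paired_t_test(pre$angle_deg[match(common, pre$subject_id)],
                        post$angle_deg[match(common, post$subject_id)],
                        paired = paired)
    ps <- stats::sd(pre$angle_deg)
    data.frame(technique = tech,
               pre_mean = mean(pre$angle_deg), pre_std = ps,
               post_mean = mean(post$angle_deg),
               post_std = stats::sd(post$angle_deg),
               mean_to_std_ratio_pre =
                 if (ps == 0) Inf else mean(pre$angle_deg) / ps,
               p_pre_vs_post = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise between-technique significance matrix
#'
#' Paired t-test for every unordered technique pair on the same subjects'
#' angles within one session. No multiple-testing correction is applied by
#' default, matching the raw-p presentation such comparisons are usually
#' given; Holm or Bonferroni adjustment is available behind `adjust`.
#'
#' @param table a cohort table.
#' @param session `"pre"` or `"post"`.
#' @param paired paired (default) or two-sample tests.
#' @param adjust `"none"` (default), `"holm"` or `"bonferroni"`.
#' @return symmetric technique x technique matrix of p values, `NA` on the
#'   diagonal.
#' @export
pairwise_matrix <- function(table, session = c("pre", "post"), paired = TRUE,
                            adjust = c("none", "holm", "bonferroni")) {
  session <- match.arg(session)
  adjust <- match.arg(adjust)
  check_cohort(table)
  sub <- table[table$session == session, , drop = FALSE]
  techs <- unique(sub$technique)
  if (length(techs) < 2L) stop("need at least 2 techniques")
  wide <- lapply(techs, function(tech) {
    s <- sub[sub$technique == tech, , drop = FALSE]
    stats::setNames(s$angle_deg, s$subject_id)
  })
  names(wide) <- techs
  m <- matrix(NA_real_, length(techs), length(techs),
              dimnames = list(techs, techs))
  pij <- list(); ij <- list(); k <- 0L
  for (i in seq_along(techs)[-length(techs)]) {
    for (j in (i + 1L):length(techs)) {
      common <- intersect(names(wide[[i]]), names(wide[[j]]))
      if (length(common) < 2L) stop("sample-size error: need >= 2 shared subjects")
      ht <- paired_t_test(wide[[i]][common], wide[[j]][common],
                          paired = paired)
      k <- k + 1L
      pij[[k]] <- ht$p
      ij[[k]] <- c(i, j)
    }
  }
  p <- unlist(pij)
  if (adjust != "none") p <- stats::p.adjust(p, method = adjust)
  for (k in seq_along(p)) {
    m[ij[[k]][1], ij[[k]][2]] <- p[k]
    m[ij[[k]][2], ij[[k]][1]] <- p[k]
  }
  m
}

#' Count significant cells of a pairwise matrix
#' @param matrix from [pairwise_matrix()].
#' @param alpha significance threshold (default 0.05).
#' @return number of significant unordered pairs.
#' @export
significant_count <- function(matrix, alpha = 0.05) {
  sum(matrix[upper.tri(matrix)] < alpha, na.rm = FALSE)
}

#' Read / write cohort tables as CSV
#'
#' Columns: `subject_id`, `session`, `technique`, `angle_deg`.
#'
#' @param path CSV path.
#' @return a validated cohort table.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort CSV not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(tab$angle_deg))))
  if (length(bad))
    stop("malformed cohort CSV: non-numeric angle_deg in data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  tab$angle_deg <- as.numeric(tab$angle_deg)
  check_cohort(tab)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @rdname read_cohort_csv
#' @param table a cohort table.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  check_cohort(table)
  hdr <- "subject_id,session,technique,angle_deg"
  rows <- sprintf("%s,%s,%s,%.6f", table$subject_id, table$session,
                  table$technique, table$angle_deg)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Plain-text cohort report
#'
#' Pre/post summary plus the per-session pairwise matrices and the count of
#' significant comparisons at `alpha`.
#'
#' @param table a cohort table.
#' @param alpha significance threshold.
#' @param paired paired or two-sample tests.
#' @return character vector of report lines.
#' @export
cohort_report <- function(table, alpha = 0.05, paired = TRUE) {
  sm <- summarize_cohort(table, paired = paired)
  lines <- c("HAA cohort report", "=================", "",
             "Per-technique summary (degrees, valgus positive):",
             utils::capture.output(print(format(sm, digits = 4),
                                         row.names = FALSE)))
  for (ses in c("pre", "post")) {
    m <- pairwise_matrix(table, ses, paired = paired)
    lines <- c(lines, "", sprintf("Pairwise p values (%s):", ses),
               utils::capture.output(print(round(m, 4))),
               sprintf("significant at alpha = %.2f: %d of %d comparisons",
                       alpha, significant_count(m, alpha),
                       sum(upper.tri(m))))
  }
  lines
}

#' Box plot of a cohort table by technique and session
#'
#' @param table a cohort table.
#' @param path optional PNG output path; when `NULL` draws on the active
#'   device.
#' @return invisibly, `path` or `NULL`.
#' @export
cohort_boxplot <- function(table, path = NULL) {
  check_cohort(table)
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old), add = TRUE)
  for (ses in c("pre", "post")) {
    sub <- table[table$session == ses, , drop = FALSE]
    graphics::boxplot(angle_deg ~ technique, data = sub,
                      main = sprintf("HAA by technique (%s)", ses),
                      ylab = "HAA (deg, valgus +)", xlab = "technique")
  }
  invisible(path)
}
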