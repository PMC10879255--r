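#' Pooled-variance two-sample Student's t test, group vs rest
#'
#' Closed form: \code{t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))} with pooled
#' variance \code{s_p^2} on \code{n1 + n2 - 2} degrees of freedom; the
#' two-sided p-value comes from the exact t distribution. When the pooled
#' variance is zero, equal means give t = 0 and p = 1, unequal means give
#' p = 0 with a warning.
#'
#' @param values numeric vector.
#' @param labels group labels aligned with \code{values}.
#' @param group the group of interest (compared against all others).
#' @param variable optional variable name carried into the output.
#' @return one-row data.frame \code{variable, mean_group, mean_rest, t, df,
#'   p, n_group, n_rest}.
#' @export
student_t <- function(values, labels, group, variable = "value") {
  in_group <- labels == group
  x <- values[in_group]; y <- values[!in_group]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both sides need at least 2 finite values")
  m1 <- mean(x); m2 <- mean(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    if (m1 == m2) {
      t <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means; p = 0")
      t <- Inf * sign(m1 - m2); p <- 0
    }
  } else {
    t <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  data.frame(variable = variable, mean_group = m1, mean_rest = m2,
             t = t, df = df, p = p, n_group = n1, n_rest = n2,
             stringsAsFactors = FALSE)
}

#' High-grade association of one group (Student's t on an indicator)
#'
#' The high-grade indicator is 1 for WHO grade 2 or 3 and 0 for grade 1;
#' the indicator is compared between the group of interest and the rest
#' with the pooled-variance t test. (Applying Student's t to a binary
#' indicator is a deliberate convention of this analysis style; a Fisher
#' exact test would be the usual categorical alternative.)
#'
#' @param metadata metadata table with a \code{who_grade} column in 1..3.
#' @param labels group labels aligned with metadata rows.
#' @param group the group of interest.
#' @return one-row [student_t()] comparison for variable
#'   \code{"high_grade"}.
#' @export
grade_association <- function(metadata, labels, group) {
  if (!all(metadata$who_grade %in% 1:3)) stop("who_grade must be in 1..3")
  ind <- as.numeric(metadata$who_grade >= 2)
  student_t(ind, labels, group, variable = "high_grade")
}

#' Proliferation-marker and mitotic-index comparisons for one group
#'
#' One pooled-variance t comparison per marker gene (per-sample TPM of the
#' marker, group vs rest) plus one for the mitotic index. Markers absent
#' from the expression matrix are listed with status \code{"absent"}
#' rather than failing.
#'
#' @param tpm_mat TPM matrix (gene x sample).
#' @param metadata metadata table with \code{mitotic_index}, rows aligned
#'   with the TPM columns.
#' @param labels group labels aligned with samples.
#' @param markers marker gene ids.
#' @param group the designated proliferative group of interest.
#' @return data.frame of comparisons with a \code{status} column
#'   (\code{"ok"} or \code{"absent"}).
#' @export
marker_summary <- function(tpm_mat, metadata, labels, markers, group) {
  rows <- lapply(markers, function(mk) {
    if (!mk %in% rownames(tpm_mat)) {
      return(data.frame(variable = mk, mean_group = NA_real_,
                        mean_rest = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, n_group = NA_integer_,
                        n_rest = NA_integer_, status = "absent",
                        stringsAsFactors = FALSE))
    }
    cmp <- student_t(as.numeric(tpm_mat[mk, ]), labels, group,
                     variable = mk)
    cmp$status <- "ok"
    cmp
  })
  mit <- student_t(metadata$mitotic_index, labels, group,
                   variable = "mitotic_index")
  mit$status <- "ok"
  out <- rbind(do.call(rbind, rows), mit)
  rownames(out) <- NULL
  out
}
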