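#' Per-subject benchmark results from a published 16-subject study
#'
#' Per-subject test-set results of a published upper-limb motor-imagery
#' study (16 healthy subjects, C3/Cz/C4 montage at 250 Hz) comparing six
#' decoding methods: broadband CSP and DFBCSP features, each paired with
#' LDA, SVM, and MLP classifiers. Four tables are shipped: classification
#' accuracy (%) and Cohen's kappa for the two-class (left-limb imagery
#' vs. rest) and three-class (left imagery, right imagery, rest) tasks.
#' These are the reference values that [column_summary()] aggregates; the
#' underlying recordings are not public.
#'
#' @param metric `"accuracy"` or `"kappa"`.
#' @param task `"twoclass"` or `"threeclass"`.
#' @return numeric matrix, 16 subjects x 6 methods (`csp_lda`, `csp_svm`,
#'   `csp_mlp`, `dfbcsp_lda`, `dfbcsp_svm`, `dfbcsp_mlp`), with subject
#'   ids as row names.
#' @export
study_table <- function(metric = c("accuracy", "kappa"),
                        task = c("twoclass", "threeclass")) {
  metric <- match.arg(metric)
  task <- match.arg(task)
  path <- system.file("extdata",
                      sprintf("study_%s_%s.tsv", metric, task),
                      package = "dfbcsp", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$subject
  m
}
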