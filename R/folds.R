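#' Ten-way stratified fold plan
#'
#' Randomly partitions a dataset into `n_folds` disjoint, exhaustive folds,
#' stratified by the joint (T, N, grade) class so every class appears in
#' every fold whenever its count allows; smaller classes are spread as evenly
#' as possible (with a warning). Each cross-validation round uses one fold
#' for testing, the next two (cyclically) for validation and the remaining
#' seven for training.
#'
#' @param ds a [raman_dataset()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the plan is deterministic given it.
#' @param group_by_patient if `TRUE`, all spectra of a patient share a fold.
#'   The default (`FALSE`) splits at spectrum level, which mirrors the usual
#'   protocol but lets a patient's spectra straddle training and testing —
#'   an optimistic bias worth remembering when reading desk-scale metrics.
#' @return an object of class `fold_plan`.
#' @export
make_folds <- function(ds, n_folds = 10L, seed = 1L,
                       group_by_patient = FALSE) {
  stopifnot(inherits(ds, "raman_dataset"), n_folds >= 2L)
  n <- nrow(ds$intensities)
  if (!n) stop("dataset is empty", call. = FALSE)
  cls <- joint_class(ds$labels)
  assignments <- integer(n)
  with_seed(seed, {
    if (group_by_patient) {
      for (cl in unique(cls)) {
        pats <- unique(ds$labels$patient_id[cls == cl])
        if (length(pats) < n_folds)
          warning(sprintf("class %s has %d patients < %d folds", cl,
                          length(pats), n_folds), call. = FALSE)
        pats <- sample(pats)
        pf <- (seq_along(pats) - 1L + sample.int(n_folds, 1L)) %% n_folds + 1L
        assignments[cls == cl] <-
          pf[match(ds$labels$patient_id[cls == cl], pats)]
      }
    } else {
      for (cl in unique(cls)) {
        idx <- which(cls == cl)
        if (length(idx) < n_folds)
          warning(sprintf("class %s has %d spectra < %d folds", cl,
                          length(idx), n_folds), call. = FALSE)
        idx <- sample(idx)
        assignments[idx] <-
          (seq_along(idx) - 1L + sample.int(n_folds, 1L)) %% n_folds + 1L
      }
    }
  })
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 seed = as.integer(seed),
                 group_by_patient = group_by_patient),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds over %d spectra (%s-level, seed %d)\n",
              x$n_folds, length(x$assignments),
              if (x$group_by_patient) "patient" else "spectrum", x$seed))
  print(table(fold = x$assignments))
  invisible(x)
}

#' Train/validation/test roles for one round
#'
#' Round `r` tests on fold `r`, validates on the next two folds (cyclically)
#' and trains on the remaining `n_folds - 3`.
#'
#' @param plan a [make_folds()] plan.
#' @param round round index in `1..n_folds`.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
fold_roles <- function(plan, round) {
  stopifnot(inherits(plan, "fold_plan"), round >= 1L,
            round <= plan$n_folds)
  test_f <- round
  val_f <- (c(round, round + 1L) %% plan$n_folds) + 1L
  a <- plan$assignments
  list(train = which(!(a %in% c(test_f, val_f))),
       val = which(a %in% val_f),
       test = which(a == test_f))
}
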