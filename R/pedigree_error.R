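#' Specification of a pedigree-error experiment
#'
#' @param rate fraction of progeny per generation whose recorded sire is
#'   replaced (0, 0.10, 0.20, 0.30 or 0.40 in the reference experiment).
#' @param generations generations whose progeny are corrupted.
#' @param seed integer seed.
#' @return An object of class `error_spec`.
#' @export
error_spec <- function(rate, generations = 1:10, seed = 1L) {
  structure(list(rate = check_fraction(rate, "rate"),
                 generations = as.integer(generations),
                 seed = as.integer(seed)),
            class = "error_spec")
}

#' Inject wrong-sire records into a recorded pedigree
#'
#' Within each targeted generation, exactly `round(rate * n)` of the `n`
#' progeny with a known recorded sire have that sire replaced by a different
#' sire drawn uniformly from the generation's candidate sire list.  Dams,
#' sexes, generations and the simulation-truth pedigree are untouched; only
#' the recorded sire field changes.  Progeny whose sire record is already
#' missing are excluded from the error-rate denominator.
#'
#' @param x a `population` or a pedigree data frame with columns `id`,
#'   `rec_sire` (or `sire`), `generation`.
#' @param spec an [error_spec()] (or a rate, for convenience).
#' @param sire_pool optional list mapping generation to candidate sire ids;
#'   defaults to the population's recorded active-sire lists, or, for a bare
#'   pedigree, to the distinct known sires observed in that generation.
#' @return For a population: the modified `population` with a `change_log`
#'   tibble attached (`pop$change_log`).  For a pedigree: a list with
#'   elements `ped` and `log` (`generation`, `animal_id`, `old_sire`,
#'   `new_sire`).
#' @export
inject_sire_errors <- function(x, spec, sire_pool = NULL) {
  if (!inherits(spec, "error_spec")) spec <- error_spec(spec)
  if (inherits(x, "population")) {
    res <- inject_sire_errors_ped(
      data.frame(id = x$ped$id, rec_sire = x$ped$rec_sire,
                 generation = x$ped$generation),
      spec, sire_pool %||% x$sire_pool)
    x$ped$rec_sire <- res$ped$rec_sire
    x$change_log <- res$log
    x
  } else {
    ped <- as.data.frame(x)
    if (!"rec_sire" %in% names(ped)) ped$rec_sire <- ped$sire
    inject_sire_errors_ped(ped, spec, sire_pool)
  }
}

inject_sire_errors_ped <- function(ped, spec, sire_pool = NULL) {
  logs <- list()
  with_seed(spec$seed, {
    for (g in spec$generations) {
      rows <- which(ped$generation == g & ped$rec_sire != 0)
      if (length(rows) == 0) next
      pool <- if (!is.null(sire_pool) && length(sire_pool) >= g &&
                  !is.null(sire_pool[[g]])) sire_pool[[g]]
              else unique(ped$rec_sire[rows])
      if (length(pool) < 2)
        stop_bad_arg("generation ", g, ": fewer than 2 candidate sires; ",
                     "cannot guarantee a wrong record")
      k <- round(spec$rate * length(rows))
      if (k == 0) next
      pick <- sort(sample(rows, k))
      old <- ped$rec_sire[pick]
      new <- vapply(old, function(s) {
        cand <- pool[pool != s]
        if (length(cand) == 1) cand else sample(cand, 1)
      }, numeric(1))
      ped$rec_sire[pick] <- as.integer(new)
      logs[[length(logs) + 1]] <- tibble::tibble(
        generation = g, animal_id = ped$id[pick],
        old_sire = as.integer(old), new_sire = as.integer(new))
    }
  })
  log <- if (length(logs)) do.call(rbind, logs) else
    tibble::tibble(generation = integer(), animal_id = integer(),
                   old_sire = integer(), new_sire = integer())
  list(ped = ped, log = log)
}
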