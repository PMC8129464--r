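#' Aggregated animal study data
#'
#' One completed animal toxicology study: the doses tested (mg/kg on the
#' species' native scale), the number of animals per dose group and the
#' number that experienced a dose-limiting toxicity (DLT).
#'
#' @param study_id Character identifier for the study.
#' @param species Species label; must belong to the species set of any
#'   [bridge_config()] the study is later analysed under (e.g. `"rat"`,
#'   `"monkey"`).
#' @param dose Strictly increasing vector of positive dose levels, mg/kg.
#' @param n Number of animals per dose group (all `>= 1`).
#' @param r Number of DLTs per dose group, `0 <= r <= n`.
#'
#' @return An object of class `animal_study`.
#' @examples
#' animal_study("m1", "monkey", c(1, 10, 30, 100), n = rep(8, 4), r = c(0, 1, 3, 6))
#' @export
animal_study <- function(study_id, species, dose, n, r) {
  stopifnot(length(study_id) == 1L, length(species) == 1L)
  dose <- as.numeric(dose); n <- as.integer(n); r <- as.integer(r)
  if (length(dose) < 1L || length(n) != length(dose) || length(r) != length(dose))
    stop("dose, n and r must be non-empty vectors of equal length")
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  if (any(n < 1L)) stop("each dose group must contain at least one animal (n >= 1)")
  if (any(r < 0L) || any(r > n)) stop("DLT counts must satisfy 0 <= r <= n")
  structure(
    list(study_id = as.character(study_id), species = as.character(species),
         dose = dose, n = n, r = r),
    class = "animal_study")
}

#' Accumulated human trial data for one subgroup
#'
#' Dose-toxicity data accrued in a single phase I trial run in one patient
#' subgroup (geographic region): the dose panel, patients treated and DLTs
#' per dose.
#'
#' @param subgroup Integer subgroup index (1-based).
#' @param dose Strictly increasing dose panel, mg/kg.
#' @param n Patients treated per dose (may be zero).
#' @param r DLTs per dose, `0 <= r <= n`.
#' @param max_patients Optional cap checked against `sum(n)`.
#'
#' @return An object of class `human_trial`.
#' @examples
#' human_trial(1, c(0.1, 0.5, 1, 5, 10, 20), n = c(3, 3, 6, 12, 0, 0),
#'             r = c(0, 0, 1, 3, 0, 0))
#' @export
human_trial <- function(subgroup, dose, n, r, max_patients = NULL) {
  dose <- as.numeric(dose); n <- as.integer(n); r <- as.integer(r)
  if (length(dose) < 1L || length(n) != length(dose) || length(r) != length(dose))
    stop("dose, n and r must be non-empty vectors of equal length")
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  if (any(n < 0L)) stop("patient counts must be non-negative")
  if (any(r < 0L) || any(r > n)) stop("DLT counts must satisfy 0 <= r <= n")
  if (!is.null(max_patients) && sum(n) > max_patients)
    stop("total patients exceed the configured maximum sample size")
  structure(
    list(subgroup = as.integer(subgroup), dose = dose, n = n, r = r),
    class = "human_trial")
}

#' @export
print.animal_study <- function(x, ...) {
  cat("Animal study", x$study_id, sprintf("(%s)\n", x$species))
  print(data.frame(dose = x$dose, n = x$n, r = x$r), row.names = FALSE)
  invisible(x)
}

#' @export
print.human_trial <- function(x, ...) {
  cat("Human trial, subgroup", x$subgroup, "\n")
  print(data.frame(dose = x$dose, n = x$n, r = x$r), row.names = FALSE)
  invisible(x)
}

#' Read and write dose-toxicity study tables
#'
#' Studies are exchanged as delimited tables with columns `study_id`,
#' `kind` (`"animal"` or `"human"`), `species_or_subgroup`, `dose`, `n`,
#' `r`.  `write_study_table()` serialises a mixed list of [animal_study()]
#' and [human_trial()] objects; `read_study_table()` reads one back.
#'
#' @param studies List of `animal_study` / `human_trial` objects.
#' @param file Path to a tab- or comma-separated file.
#' @param sep Field separator (default tab).
#' @return `read_study_table()` returns a list with elements `animal` and
#'   `human`.
#' @export
write_study_table <- function(studies, file, sep = "\t") {
  rows <- lapply(studies, function(s) {
    if (inherits(s, "animal_study"))
      data.frame(study_id = s$study_id, kind = "animal",
                 species_or_subgroup = s$species, dose = s$dose, n = s$n, r = s$r)
    else if (inherits(s, "human_trial"))
      data.frame(study_id = paste0("T", s$subgroup), kind = "human",
                 species_or_subgroup = as.character(s$subgroup),
                 dose = s$dose, n = s$n, r = s$r)
    else stop("studies must be animal_study or human_trial objects")
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(file, sep = "\t") {
  tab <- utils::read.table(file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("study_id", "kind", "species_or_subgroup", "dose", "n", "r")
  if (!all(need %in% names(tab))) stop("missing required columns: ",
                                       paste(setdiff(need, names(tab)), collapse = ", "))
  animal <- list(); human <- list()
  for (id in unique(tab$study_id[tab$kind == "animal"])) {
    sub <- tab[tab$study_id == id & tab$kind == "animal", ]
    sub <- sub[order(sub$dose), ]
    animal[[length(animal) + 1L]] <-
      animal_study(id, sub$species_or_subgroup[1L], sub$dose, sub$n, sub$r)
  }
  for (id in unique(tab$study_id[tab$kind == "human"])) {
    sub <- tab[tab$study_id == id & tab$kind == "human", ]
    sub <- sub[order(sub$dose), ]
    human[[length(human) + 1L]] <-
      human_trial(as.integer(sub$species_or_subgroup[1L]), sub$dose, sub$n, sub$r)
  }
  list(animal = animal, human = human)
}
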