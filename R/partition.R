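#' Partition a growth dataset into partial and validation sets
#'
#' Builds the partial (training) record set and the validation target surface
#' for one of three deterministic partitioning scenarios:
#'
#' * `"between_animals"`: all records of the first third of the animals (the
#'   500 of 1,500 at full scale) form the partial set; the remaining animals
#'   are the validation set, with the validation EBV surface spanning every
#'   recorded age.
#' * `"by_age_within_animals"`: records up to `age_cut` (default day 300) of
#'   every animal form the partial set; all animals are validation animals
#'   and the validation surface spans the withheld ages (> `age_cut`).
#' * `"between_animals_and_by_age"`: records up to `age_cut` of the first
#'   third of the animals form the partial set; the remaining animals at the
#'   withheld ages are the validation target.
#'
#' "First" animals means lowest animal ids — partitioning involves no
#' randomness. Under reduced-scale configurations the animal cut scales
#' proportionally (`train_frac`) while the day-300 age cut is unchanged
#' because reduced designs keep the 70-500 day range and only thin the
#' recording cadence.
#'
#' @param dataset A `growth_dataset`.
#' @param scenario One of `"between_animals"`, `"by_age_within_animals"`,
#'   `"between_animals_and_by_age"`.
#' @param train_frac Fraction of animals assigned to training in the
#'   between-animal splits (default 1/3, the 500/1500 design).
#' @param age_cut Last training day for the by-age splits (default 300;
#'   training uses ages `<= age_cut`, the validation surface ages
#'   `> age_cut`).
#' @return An object of class `growth_partition`: list with `scenario`,
#'   `partial_records` (tibble `animal`, `age`, `weight`),
#'   `training_animals`, `validation_animals`, `validation_ages`,
#'   `train_frac`, `age_cut`.
#' @examples
#' ds <- simulate_growth(sim_config(n_animals = 30, scale = "desk"), seed = 1)
#' part <- make_partition(ds, "between_animals")
#' length(part$validation_animals)
#' @export
make_partition <- function(dataset,
                           scenario = c("between_animals",
                                        "by_age_within_animals",
                                        "between_animals_and_by_age"),
                           train_frac = 1 / 3, age_cut = 300L) {
  stopifnot(inherits(dataset, "growth_dataset"))
  scenario <- match.arg(scenario)
  records <- dataset$records
  animals <- sort(unique(records$animal))
  ages <- sort(unique(records$age))
  n_trn <- max(1L, round(train_frac * length(animals)))
  first <- animals[seq_len(n_trn)]
  rest <- setdiff(animals, first)
  partial <- switch(scenario,
    between_animals = dplyr::filter(records, .data$animal %in% first),
    by_age_within_animals = dplyr::filter(records, .data$age <= age_cut),
    between_animals_and_by_age =
      dplyr::filter(records, .data$animal %in% first, .data$age <= age_cut))
  val_animals <- switch(scenario,
    between_animals = rest,
    by_age_within_animals = animals,
    between_animals_and_by_age = rest)
  val_ages <- switch(scenario,
    between_animals = ages,
    by_age_within_animals = ages[ages > age_cut],
    between_animals_and_by_age = ages[ages > age_cut])
  stopifnot(nrow(partial) > 0, length(val_animals) > 0, length(val_ages) > 0)
  structure(list(scenario = scenario, partial_records = partial,
                 training_animals = sort(unique(partial$animal)),
                 validation_animals = val_animals,
                 validation_ages = val_ages,
                 train_frac = train_frac, age_cut = as.integer(age_cut)),
            class = "growth_partition")
}

#' @export
print.growth_partition <- function(x, ...) {
  cat("<growth_partition> '", x$scenario, "': ", nrow(x$partial_records),
      " partial records, ", length(x$training_animals), " training animals, ",
      length(x$validation_animals), " validation animals x ",
      length(x$validation_ages), " validation ages\n", sep = "")
  invisible(x)
}

#' Tabulate set membership of every record
#'
#' Long audit table marking each (animal, age) record of the dataset as
#' belonging to the partial set and/or the validation target surface of a
#' partition. Suitable for writing to CSV.
#'
#' @param partition A `growth_partition`.
#' @param dataset The `growth_dataset` it was built from.
#' @return A tibble with columns `animal`, `age`, `in_partial`,
#'   `in_validation_target`.
#' @export
partition_membership <- function(partition, dataset) {
  stopifnot(inherits(partition, "growth_partition"),
            inherits(dataset, "growth_dataset"))
  key_p <- paste(partition$partial_records$animal,
                 partition$partial_records$age)
  dataset$records |>
    dplyr::select("animal", "age") |>
    dplyr::mutate(
      in_partial = paste(.data$animal, .data$age) %in% key_p,
      in_validation_target = .data$animal %in% partition$validation_animals &
        .data$age %in% partition$validation_ages)
}
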