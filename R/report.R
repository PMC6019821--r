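#' Inside/outside-hotnode summary report
#'
#' Produces Table-style counts and intensities for the species inside
#' hotnode clades, outside them, and overall.  Per partition:
#'
#' * `n_species`, `n_species_used` — flora size and species with
#'   ethnomedicinal use;
#' * `n_used_species_studied` — used species with at least one
#'   pharmacological study;
#' * `n_genera`, `n_genera_used`, `n_genera_studied` — genus-level
#'   presence/any-species aggregation (a genus is "used" if any of its
#'   species is used, "studied" if any is studied); a genus straddling the
#'   hotnode boundary is counted in both partitions, so genus rows may sum
#'   to more than the total;
#' * `sum_use_reports` — total use reports (intensity of traditional use);
#' * `sum_studies_used` — studies summed over used species (intensity of
#'   research effort on ethnomedicinal species);
#' * `mean_studies_per_studied_species` — `sum_studies_used` divided by
#'   the number of used-and-studied species.
#'
#' Derived percentages are reported with explicit numerators and
#' denominators, both raw and display-rounded (round-half-up to integer),
#' because shares like "percent of used species studied" and "percent of
#' flora inside hotnodes" use different denominators and rounding
#' conventions vary between reports.
#'
#' @param dataset A `"species_dataset"`.
#' @param inside Character vector of species inside hotnode clades (e.g.
#'   `hotnode_set$inside`, or from [read_membership()]).  Species of the
#'   dataset absent from `inside` are treated as outside; elements of
#'   `inside` absent from the dataset are reported in the `unmatched`
#'   field.
#' @return An object of class `"summary_report"`: list with `partitions`
#'   (data frame with rows inside/outside/total), `percentages` (data
#'   frame: name, numerator, denominator, raw, display) and `unmatched`.
#' @export
summarize_use <- function(dataset, inside) {
  stopifnot(inherits(dataset, "species_dataset"))
  inside <- as.character(inside)
  unmatched <- setdiff(inside, dataset$species)
  is_in <- dataset$species %in% inside

  part_stats <- function(sub) {
    used <- sub[sub$used, , drop = FALSE]
    studied_used <- used[used$n_studies > 0, , drop = FALSE]
    genera <- unique(sub$genus)
    data.frame(
      n_species = nrow(sub),
      n_species_used = nrow(used),
      n_used_species_studied = nrow(studied_used),
      n_genera = length(genera),
      n_genera_used = length(unique(used$genus)),
      n_genera_studied = length(unique(sub$genus[sub$n_studies > 0])),
      sum_use_reports = sum(sub$n_use_reports),
      sum_studies_used = sum(used$n_studies),
      mean_studies_per_studied_species =
        if (nrow(studied_used)) sum(used$n_studies) / nrow(studied_used) else 0
    )
  }
  parts <- rbind(
    inside = part_stats(dataset[is_in, , drop = FALSE]),
    outside = part_stats(dataset[!is_in, , drop = FALSE]),
    total = part_stats(dataset)
  )
  parts <- cbind(partition = rownames(parts), parts)
  rownames(parts) <- NULL

  tot <- parts[parts$partition == "total", ]
  ins <- parts[parts$partition == "inside", ]
  unused_genera <- setdiff(unique(dataset$genus), unique(dataset$genus[dataset$used]))
  unused_genera_studied <-
    intersect(unused_genera, unique(dataset$genus[dataset$n_studies > 0]))

  pct <- function(name, num, den)
    data.frame(name = name, numerator = num, denominator = den,
               raw = if (den > 0) 100 * num / den else 0,
               display = if (den > 0) round_half_up(100 * num / den) else 0)
  percentages <- rbind(
    pct("pct_flora_used", tot$n_species_used, tot$n_species),
    pct("pct_used_species_studied", tot$n_used_species_studied, tot$n_species_used),
    pct("pct_used_genera_studied",
        length(intersect(unique(dataset$genus[dataset$used]),
                         unique(dataset$genus[dataset$n_studies > 0]))),
        tot$n_genera_used),
    pct("pct_unused_genera_studied", length(unused_genera_studied),
        length(unused_genera)),
    pct("pct_used_species_inside", ins$n_species_used, tot$n_species_used),
    pct("pct_species_inside", ins$n_species, tot$n_species),
    pct("pct_inside_species_used", ins$n_species_used, ins$n_species),
    pct("pct_outside_species_used",
        tot$n_species_used - ins$n_species_used,
        tot$n_species - ins$n_species)
  )
  structure(list(partitions = parts, percentages = percentages,
                 unmatched = unmatched),
            class = "summary_report")
}

round_half_up <- function(x) floor(x + 0.5)

#' @export
print.summary_report <- function(x, ...) {
  cat("Inside/outside hotnode summary\n")
  print(x$partitions, row.names = FALSE)
  cat("\nShares (raw %, display %):\n")
  print(x$percentages, row.names = FALSE)
  if (length(x$unmatched))
    cat("\nunmatched inside species:", length(x$unmatched), "\n")
  invisible(x)
}

#' Overlap between drug-yielding genera and the ethnoflora
#'
#' Intersects a list of genera known to yield approved or clinical-trial
#' drugs with (a) the genera having at least one ethnomedicinally used
#' species and (b) the genera with used species falling inside hotnode
#' clades.
#'
#' @param dataset A `"species_dataset"`.
#' @param drug_genera Character vector of genus names.
#' @param inside Character vector of species inside hotnode clades.
#' @return A list: `n_drug_genera`, `n_with_use`, `n_in_hotnodes`, and
#'   the corresponding genus vectors `with_use`, `in_hotnodes`.
#' @export
drug_overlap <- function(dataset, drug_genera, inside) {
  stopifnot(inherits(dataset, "species_dataset"))
  drug_genera <- unique(as.character(drug_genera))
  used_genera <- unique(dataset$genus[dataset$used])
  hot_genera <- unique(dataset$genus[dataset$species %in% inside])
  with_use <- intersect(drug_genera, used_genera)
  in_hot <- intersect(with_use, hot_genera)
  list(n_drug_genera = length(drug_genera),
       n_with_use = length(with_use),
       n_in_hotnodes = length(in_hot),
       with_use = with_use,
       in_hotnodes = in_hot)
}
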