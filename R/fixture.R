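#' Synthetic flora with the count structure of a large legume ethnoflora
#'
#' Builds, entirely in code, a deterministic species table plus hotnode
#' membership that reproduces the summary count structure typical of a
#' large tropical legume flora: 2837 species in 222 genera; 286 species
#' (about 10% of the flora) with ethnomedicinal use in 104 genera; half of
#' the used species (143) the subject of at least one pharmacological
#' study; 22 of the 118 genera without any recorded use nevertheless
#' studied; hotnode clades covering 454 species (16% of the flora) that
#' contain 126 used species (44% of all used species); and use-report /
#' study totals of 1192 and 1028 inside the hotnode clades versus 549 and
#' 1665 outside.  Fourteen genera that yield FDA-approved or
#' clinical-trial drugs are included by name, eleven of them with
#' ethnomedicinal use and two of those (*Senna*, *Vachellia*) inside
#' hotnode clades.
#'
#' The table is synthetic: genus sizes and per-species counts are spread
#' deterministically so that the marginal totals above hold exactly, which
#' makes the fixture suitable for exercising and checking the reporting
#' arithmetic, not for any biological inference.
#'
#' @return A list: `dataset` (a `"species_dataset"`), `inside` (character
#'   vector of hotnode-clade species), `drug_genera` (the 14 genus names).
#' @examples
#' fx <- synthetic_flora()
#' summarize_use(fx$dataset, fx$inside)
#' @export
synthetic_flora <- function() {
  drug_used_hot <- c("Senna", "Vachellia")
  drug_used_out <- c("Acacia", "Senegalia", "Melilotus", "Mucuna", "Crotalaria",
                     "Sophora", "Phaseolus", "Vigna", "Indigofera")
  drug_unused <- c("Trifolium", "Lonchocarpus", "Pueraria")
  drug_genera <- c(drug_used_hot, drug_used_out, drug_unused)

  # genus roster: 35 hotnode genera (all used), 69 used genera outside,
  # 118 unused genera
  hot_genera <- c(drug_used_hot, sprintf("Hotgenus%02d", seq_len(33)))
  out_used_genera <- c(drug_used_out, sprintf("Usedgenus%02d", seq_len(60)))
  unused_genera <- c(drug_unused, sprintf("Othergenus%03d", seq_len(115)))

  # genus sizes: hotnode genera 34x13 + 1x12 = 454 species (all inside);
  # remaining 187 genera 139x13 + 48x12 = 2383 species -> 2837 total
  hot_sizes <- c(rep(13L, 34), 12L)
  rest_sizes <- c(rep(13L, 139), rep(12L, 48))
  rest_genera <- c(out_used_genera, unused_genera)
  stopifnot(sum(hot_sizes) == 454L, sum(rest_sizes) == 2383L,
            length(rest_sizes) == length(rest_genera))

  # used species per genus: hotnode 21x4 + 14x3 = 126;
  # outside used genera 22x3 + 47x2 = 160; unused genera 0
  hot_used <- c(rep(4L, 21), rep(3L, 14))
  out_used <- c(rep(3L, 22), rep(2L, 47), rep(0L, length(unused_genera)))

  genus <- rep(c(hot_genera, rest_genera), times = c(hot_sizes, rest_sizes))
  sizes <- c(hot_sizes, rest_sizes)
  n_used_per_genus <- c(hot_used, out_used)
  used <- unlist(mapply(function(size, nu) c(rep(TRUE, nu), rep(FALSE, size - nu)),
                        sizes, n_used_per_genus, SIMPLIFY = FALSE))
  species <- paste0(genus, "_sp", unlist(lapply(sizes, seq_len)))
  inside <- species[genus %in% hot_genera]

  df <- data.frame(species = species, genus = genus, used = used,
                   n_use_reports = 0L, n_studies = 0L, categories = "",
                   stringsAsFactors = FALSE)
  is_in <- df$species %in% inside

  # use reports: inside used species sum to 1192 (58x10 + 68x9),
  # outside used sum to 549 (69x4 + 91x3)
  df$n_use_reports[df$used & is_in] <- rep(c(10L, 9L), c(58, 68))
  df$n_use_reports[df$used & !is_in] <- rep(c(4L, 3L), c(69, 91))

  # studies on used species: 74 inside summing 1028 (66x14 + 8x13) spread
  # over 34 genera, 69 outside summing 1665 (9x25 + 60x24) over 42 genera
  pick_studied <- function(genera, quota) {
    unlist(mapply(function(g, q) which(df$genus == g & df$used)[seq_len(q)],
                  genera, quota, SIMPLIFY = FALSE))
  }
  in_studied <- pick_studied(hot_genera[seq_len(34)], rep(c(3L, 1L), c(20, 14)))
  out_studied <- pick_studied(out_used_genera[seq_len(42)], rep(c(2L, 1L), c(27, 15)))
  stopifnot(length(in_studied) == 74L, length(out_studied) == 69L)
  df$n_studies[in_studied] <- rep(c(14L, 13L), c(66, 8))
  df$n_studies[out_studied] <- rep(c(25L, 24L), c(9, 60))

  # 22 unused genera with one studied species each (including the three
  # unused drug-yielding genera)
  studied_unused <- c(drug_unused, sprintf("Othergenus%03d", seq_len(19)))
  for (g in studied_unused) {
    i <- which(df$genus == g & !df$used)[1L]
    df$n_studies[i] <- 1L
  }

  # therapeutic-application codes for the named drug genera
  codes <- c(Senna = "DDS;DRS;DCS", Vachellia = "DDS;DMC;DRS",
             Senegalia = "DRS;DMC;IPD", Acacia = "DFS", Crotalaria = "DFS;IPD",
             Mucuna = "Medicinal", Melilotus = "Medicinal", Sophora = "Medicinal",
             Phaseolus = "ENM;IPD", Vigna = "DSS", Indigofera = "DDS;DGS")
  for (g in names(codes)) {
    i <- which(df$genus == g & df$used)
    df$categories[i] <- codes[[g]]
  }

  list(dataset = species_dataset(df), inside = inside, drug_genera = drug_genera)
}
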