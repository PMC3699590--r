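# Reference region statistics for an adult rabbit brain parcellation:
# volume fraction (% of brain), relative T1 intensity (brain mean = 1),
# fractional anisotropy, and relative mean diffusivity, with inter-subject
# SDs. Used as the default parameterization of the synthetic generator and
# to build the default region table.
rabbit_region_stats <- function() {
  txt <- "name|group|bilateral|vol|vol_sd|t1|t1_sd|fa|fa_sd|md|md_sd
Frontal cortex|cortical|1|7.89|0.65|0.93|0.05|0.18|0.06|1.00|0.20
Medial frontal cortex|cortical|1|2.45|0.09|0.94|0.08|0.18|0.04|1.07|0.09
Cingulate cortex|cortical|1|2.86|0.30|0.83|0.06|0.15|0.04|1.08|0.06
Piriform cortex|cortical|1|3.77|0.19|0.87|0.04|0.19|0.04|1.03|0.14
Entorhinal cortex|cortical|1|1.40|0.09|0.75|0.05|0.15|0.02|1.15|0.12
Parietal cortex|cortical|1|5.59|0.40|0.86|0.02|0.16|0.03|1.07|0.06
Occipital cortex|cortical|1|3.35|0.23|0.80|0.03|0.15|0.04|1.16|0.11
Insular cortex|cortical|1|0.66|0.08|0.86|0.07|0.21|0.07|1.06|0.17
Temporal cortex|cortical|1|5.92|0.24|0.82|0.04|0.13|0.02|1.08|0.05
External capsule|white_matter|1|0.43|0.04|0.95|0.08|0.28|0.03|1.07|0.06
Internal capsule|white_matter|1|1.49|0.09|1.28|0.07|0.35|0.05|0.97|0.08
Corpus callosum|white_matter|0|0.70|0.09|1.15|0.03|0.24|0.04|1.04|0.09
Anterior commissure|white_matter|0|0.13|0.02|1.30|0.05|0.27|0.04|0.96|0.09
Periventricular WM|white_matter|1|0.65|0.03|1.16|0.06|0.26|0.04|1.04|0.07
Subcortical WM|white_matter|1|2.82|0.33|1.04|0.03|0.21|0.03|1.04|0.06
Corona radiata|white_matter|1|1.59|0.13|1.17|0.05|0.23|0.06|1.06|0.09
Fimbria of hippocampus|white_matter|1|0.39|0.06|1.22|0.05|0.31|0.14|1.01|0.08
Fornix|white_matter|0|0.07|0.01|1.28|0.04|0.22|0.03|0.92|0.08
Claustrum|deep_gray|1|0.17|0.02|0.99|0.06|0.32|0.08|1.01|0.10
Caudate nucleus|deep_gray|1|1.43|0.11|1.08|0.03|0.23|0.05|1.07|0.05
Thalamus|deep_gray|1|6.86|0.39|1.21|0.05|0.23|0.02|0.97|0.03
Hippocampus|deep_gray|1|9.39|0.32|0.92|0.02|0.19|0.02|1.07|0.03
Amygdala|deep_gray|1|1.26|0.11|0.98|0.03|0.21|0.06|1.00|0.04
Hypothalamus|deep_gray|0|0.67|0.08|1.09|0.04|0.20|0.04|0.96|0.13
Lenticular nucleus|deep_gray|1|0.69|0.07|1.18|0.05|0.30|0.07|1.03|0.12
Olfactory bulb|deep_gray|1|1.59|0.41|0.76|0.05|0.12|0.06|0.61|0.03
Cerebellar hemispheres|other|1|6.47|0.82|0.85|0.02|0.11|0.03|0.95|0.13
Vermis|other|0|8.08|0.57|1.02|0.04|0.14|0.01|0.92|0.10
Basal forebrain|other|1|1.65|0.16|1.13|0.03|0.26|0.04|0.95|0.07
Forebrain|other|1|0.23|0.02|1.19|0.03|0.28|0.05|0.94|0.11
Diencephalon|other|0|0.17|0.03|1.11|0.11|0.18|0.05|1.15|0.45
Mesencephalon|other|0|8.17|0.54|1.14|0.03|0.19|0.01|0.96|0.05
Pons|other|0|5.94|0.33|1.25|0.06|0.22|0.01|0.98|0.11
Medulla oblongata|other|0|4.13|0.53|1.17|0.05|0.18|0.03|0.78|0.08
Septum|other|0|0.88|0.06|1.07|0.03|0.23|0.02|1.02|0.06"
  df <- utils::read.delim(text = txt, sep = "|", stringsAsFactors = FALSE)
  df$bilateral <- df$bilateral == 1L
  df
}

#' Default rabbit-like region table
#'
#' A 60-entry parcellation table modeled on an adult rabbit brain: 25
#' bilateral structures listed as separate left/right regions plus 10
#' midline structures, classified into cortical, white-matter, deep gray and
#' other groups. Merging the left/right pairs (see [merge_bilateral()])
#' yields 35 regions.
#'
#' @return A [region_table()] with 60 rows.
#' @export
default_region_table <- function() {
  st <- rabbit_region_stats()
  rows <- list()
  next_id <- 1L
  for (i in seq_len(nrow(st))) {
    if (st$bilateral[i]) {
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = next_id, name = paste0(st$name[i], " (left)"),
        group = st$group[i], hemisphere = "left")
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = next_id + 1L, name = paste0(st$name[i], " (right)"),
        group = st$group[i], hemisphere = "right")
      next_id <- next_id + 2L
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = next_id, name = st$name[i],
        group = st$group[i], hemisphere = "midline")
      next_id <- next_id + 1L
    }
  }
  region_table(do.call(rbind, rows))
}

#' Default synthetic region specifications
#'
#' The twelve regions used by the default synthetic phantom, with target
#' volume fraction (of the whole phantom brain), relative T1 mean and noise
#' SD, FA and relative MD targets taken from the rabbit reference
#' statistics. The set is chosen so the volume-weighted mean relative T1 is
#' ~1, keeping relative intensities directly comparable with the reference
#' values.
#'
#' @return Data frame with columns `region_id`, `name`, `group`,
#'   `hemisphere`, `vol_frac`, `t1`, `t1_sd`, `fa`, `md`.
#' @export
default_region_specs <- function() {
  st <- rabbit_region_stats()
  pick <- c("Frontal cortex", "Parietal cortex", "Temporal cortex",
            "Occipital cortex", "Internal capsule", "Corona radiata",
            "Corpus callosum", "Mesencephalon", "Vermis",
            "Thalamus", "Hippocampus", "Caudate nucleus")
  st <- st[match(pick, st$name), ]
  data.frame(region_id = seq_len(nrow(st)),
             name = st$name,
             group = st$group,
             hemisphere = "midline",
             vol_frac = st$vol / 100,
             t1 = st$t1,
             t1_sd = st$t1_sd,
             fa = st$fa,
             md = st$md,
             stringsAsFactors = FALSE)
}
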