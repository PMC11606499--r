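#!/usr/bin/env Rscript
# Generate zero-noise synthetic shells for the five forms, run the full
# segmentation -> classification pipeline, and verify each model
# reproduces its own generation manifest (capsomere census, interface
# classes).

suppressMessages(library(bmcshell))
dir.create("results", showWarnings = FALSE)

forms <- list(
  list(name = "T9",    h = 3, k = 0),
  list(name = "T9Q12", h = 3, k = 0, hp = 4, kp = 0),
  list(name = "T13",   h = 3, k = 1),
  list(name = "T16",   h = 4, k = 0),
  list(name = "T19",   h = 3, k = 2))

rows <- lapply(forms, function(f) {
  sh <- generate_shell(f$h, f$k, f$hp, f$kp, seed = 1)
  an <- analyze_shell(sh)
  man <- sh$manifest
  data.frame(form = f$name,
             capsomeres_manifest = nrow(man$sites),
             capsomeres_segmented = length(an$capsomeres),
             hexamers = an$composition$n_hexamers,
             pentamers = an$composition$n_pentamers,
             unknown = an$composition$n_unknown,
             classes_manifest = nrow(man$classes),
             classes_recovered = nrow(an$classes$classes),
             diameter_diag_A = round(an$diameters[["diagonal_average"]], 1),
             diameter_circ_A = round(an$diameters[["circumsphere"]], 1))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/synthetic_roundtrip.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Synthetic-shell round trip (segmentation vs generation manifest):\n")
print(tab, row.names = FALSE)
ok <- with(tab, all(capsomeres_manifest == capsomeres_segmented &
                      unknown == 0 & classes_manifest == classes_recovered))
cat(if (ok) "\nEvery form reproduces its manifest exactly.\n"
    else "\nWARNING: round-trip mismatch above.\n")
cat("At 65 A capsomere spacing the faceted T=9 shell measures ~37 nm\n",
    "across its pentamer vertices, matching the expected midi-shell size\n",
    "scale; larger forms grow with sqrt(T).\n", sep = "")
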