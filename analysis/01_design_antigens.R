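#!/usr/bin/env Rscript
# Antigen design stage: build dinucleotide-repeat candidates starting from
# the dTdC seed, apply the mutation scheme (T -> A, C -> T), screen for
# self-complementarity / hairpins / GC content, place LNA by the separated
# rule, and estimate duplex Tm. Also re-screens the printed SEQ1-SEQ8 panel.
# Writes: results/design_candidates.tsv, results/panel_screens.tsv,
#         results/design_candidates.fa

library(oligoantigen)
dir.create("results", showWarnings = FALSE)
seed <- 2016L

# seed repeat and its documented mutations
tc <- repeat_spec("TC", 21)
specs <- list(tc,
              mutate_repeat_unit(tc, "T", "A"),   # -> AC repeat
              mutate_repeat_unit(tc, "C", "T"),   # -> TT repeat
              repeat_spec("TC", 10), repeat_spec("TC", 63))

cands <- design_pipeline(list(repeats = specs, seed = seed))
summ <- design_summary(cands)
write.table(summ, "results/design_candidates.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_lna_fasta(lapply(cands, `[[`, "strand"), "results/design_candidates.fa")

cat(sprintf("design: %d/%d repeat specs yielded screen-passing candidates\n",
            nrow(summ), length(specs)))
cat(sprintf("  Tm range %.1f-%.1f degC; all per-LNA increments >= 2 degC: %s\n",
            min(summ$tm_celsius), max(summ$tm_celsius),
            all(vapply(cands, function(x) x$tm$delta_per_lna >= 2, NA))))

# screen the printed panel for reference
fx <- fixture_sequences()
panel <- do.call(rbind, lapply(paste0("SEQ", 1:8), function(nm) {
  s <- fx[[nm]]
  sc <- screen_strand(s)
  data.frame(name = nm, length = length(s$bases),
             n_lna = length(s$lna_flags),
             gc_percent = round(sc$gc_percent, 1),
             self_dimer_run = sc$self_dimer_run,
             hairpins = nrow(sc$hairpin_hits),
             passed = sc$passed)
}))
write.table(panel, "results/panel_screens.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("panel: %d/8 printed sequences pass the default screens\n",
            sum(panel$passed)))
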