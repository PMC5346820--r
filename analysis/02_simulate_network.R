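#!/usr/bin/env Rscript
# Step 2 — generate the synthetic interaction dataset the rest of the
# workflow runs on: 200 genes (57 isolated, 1 pair, 141-node main
# component of three communities), two planted intra-community hubs, two
# planted bridge nodes, sub-cutoff decoy records, and an annotation term
# set with one planted enriched term for the planted panel.

library(ppipanel)

seed <- 1L
in_dir <- file.path("results", "synthetic", "input")
dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = seed)
g <- generate_network(spec)
write_interactions(g$records, file.path(in_dir, "interactions.tsv"))
writeLines(g$universe, file.path(in_dir, "universe.txt"))

ann <- generate_annotations(g$universe, g$truth$hub_bottlenecks,
                            n_terms = 200L, planted_hits = 2L,
                            planted_term_size = 5L, seed = seed)
write_annotation_terms(ann$terms, file.path(in_dir, "terms.gmt"))
writeLines(g$truth$hub_bottlenecks, file.path(in_dir, "query.txt"))
jsonlite::write_json(g$truth, file.path(in_dir, "ground_truth.json"),
                     auto_unbox = TRUE, pretty = TRUE)

message(nrow(g$records), " interaction records over ",
        length(g$universe), " genes (", sum(g$records$score < 0.5),
        " decoys below the 0.5 cutoff)")
message("planted hubs: ",
        paste(setdiff(g$truth$hub_nodes, g$truth$bridge_nodes),
              collapse = ", "),
        "; planted bridges: ",
        paste(g$truth$bridge_nodes, collapse = ", "))
message("written: ", in_dir)
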