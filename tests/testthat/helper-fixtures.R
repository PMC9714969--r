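# Shared fixture builders (all data generated in code).

# Minimal well-formed subject table.
toy_subjects <- function() {
  data.frame(
    subject_id = c("a1", "a2", "b1", "b2", "c1"),
    species = c("Aotus azarae", "Aotus azarae", "Pan paniscus",
                "Pan paniscus", "Macaca mulatta"),
    clade = c("Platyrrhini", "Platyrrhini", "Hominoidea", "Hominoidea",
              "Cercopithecoidea"),
    sex = c("F", "M", "F", "M", "F"),
    age_class = c("adult", "juvenile", "adult", "infant", "adult"),
    left_insertions = c(10L, 40L, 5L, 18L, 22L),
    right_insertions = c(25L, 20L, 45L, 20L, 30L),
    bouts = c(8L, 12L, 10L, 6L, 7L),
    stringsAsFactors = FALSE)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Subject cohort drawn from a single species with per-subject p(right) = p.
null_cohort <- function(n_subjects, insertions = 100, p = 0.5,
                        species = "Testus testus") {
  right <- rbinom(n_subjects, insertions, p)
  data.frame(
    subject_id = sprintf("s%04d", seq_len(n_subjects)),
    species = species, genus = "Testus", clade = "Platyrrhini",
    sex = "F", age_class = "adult",
    left_insertions = insertions - right, right_insertions = right,
    bouts = 10L, stringsAsFactors = FALSE)
}

# Balanced five-tip ultrametric tree used across phylo tests.
tree5 <- function() {
  tubetask::parse_newick("((A:1,B:1):1,((C:0.5,D:0.5):0.5,E:1):1);")
}
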