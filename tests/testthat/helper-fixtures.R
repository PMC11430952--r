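# Shared synthetic fixtures built in code at test time.

# a template/reference pair at default geometry
default_reference <- function(seed = 101, ...) {
  make_reference_its(its_template(seed = seed, ...))
}

# a varied pool of mutation scenarios with their generating specs;
# used by the round-trip tests
mutation_scenarios <- function() {
  list(
    none = list(),
    ts_58_5p = list(mutation_spec("M58S_5p", "transition", 6)),
    ts_58_5p_p1 = list(mutation_spec("M58S_5p", "transition", 1)),
    tv_58_3p = list(mutation_spec("M58S_3p", "transversion", 7)),
    ts_18s = list(mutation_spec("M18S", "transition", 5)),
    tv_28s = list(mutation_spec("M28S", "transversion", 7)),
    ins_58 = list(mutation_spec("M58S_5p", "insertion", count = 1)),
    ins2_58 = list(mutation_spec("M58S_3p", "insertion", count = 2)),
    del_58 = list(mutation_spec("M58S_5p", "deletion", count = 1)),
    kill_18s = list(mutation_spec("M18S", "transition", 2),
                    mutation_spec("M18S", "transversion", 6)),
    kill_58_5p = list(mutation_spec("M58S_5p", "transition", 1),
                      mutation_spec("M58S_5p", "transition", 3)),
    kill_28s = list(mutation_spec("M28S", "transversion", 1),
                    mutation_spec("M28S", "transition", 4)),
    trunc_5p = list(mutation_spec("M18S", "truncate_5p", count = 4)),
    trunc_3p = list(mutation_spec("M28S", "truncate_3p", count = 6)),
    combo = list(mutation_spec("M18S", "transition", 5),
                 mutation_spec("M58S_5p", "insertion", count = 1))
  )
}

# five-tip alignment with two partitions for distance/pipeline tests
small_study_alignment <- function(seed = 7, its1_len = 200, len58 = 100) {
  tr <- ape::read.tree(
    text = "(((a:0.05,b:0.05):0.2,(c:0.05,d:0.05):0.2):0.05,e:0.3);")
  simulate_alignment_on_tree(tr, list(
    list(name = "ITS1", length = its1_len,
         model = substitution_model("TVM", gamma_shape = 0.8)),
    list(name = "5.8S", length = len58,
         model = substitution_model("SYM", gamma_shape = 0.5))), seed = seed)
}
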