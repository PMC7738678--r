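# Fixture builders shared across the test files. Everything is generated
# in code; no stored data.

# a well-formed RUNX2-like N terminus: leader + N flank + polyQ + spacer +
# polyA + C flank + tail
make_seq <- function(q = 10, a = 5, spacer = "E",
                     n_flank = "MSDVS", c_flank = "VPRLR",
                     leader = "MRIPK", tail = "GGTTNNGGTTNN",
                     q_text = strrep("Q", q), a_text = strrep("A", a)) {
  paste0(leader, n_flank, q_text, if (nzchar(q_text) && nzchar(a_text)) spacer,
         a_text, c_flank, tail)
}

make_record <- function(id = "t1", clade = "testclade", ...) {
  list(id = id, taxon = paste0(id, "_taxon"), clade = clade,
       seq = make_seq(...))
}

make_domain <- function(...) {
  assemble_domain(extract_qa_region(make_record(...)))
}

random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                      "G", "H", "I", "L", "K", "M", "F",
                                      "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# 5-leaf rooted binary caterpillar with unit branch lengths
five_leaf_tree <- function() {
  ape::read.tree(text = "((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
}

# dated 8-leaf vertebrate-style toy tree: gnathostome root at 460 Ma,
# amniote stem 350 -> 312 Ma
vertebrate_toy_tree <- function() {
  txt <- paste0(
    "(shark:460,(teleost:430,(lungfish:415,(amphibian:350,",
    "((lizard:280,bird:280):32,(marsupial:160,eutherian:160):152):38",
    "):65):15):30);")
  read_newick_text(txt)
}

read_newick_text <- function(txt) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(txt, tf)
  on.exit(unlink(tf))
  read_newick(tf)
}

vertebrate_toy_states <- function() {
  c(shark = "PROTO", teleost = "PRIMITIVE", lungfish = "PRIMITIVE",
    amphibian = "PRIMITIVE", lizard = "VARIABLE", bird = "VARIABLE",
    marsupial = "VARIABLE", eutherian = "VARIABLE")
}
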