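test_that("make_open builds feet and legs and checks ranges", {
  sir <- fixture("sir")
  o <- make_open(sir, list(1L, 2L, 3L))
  expect_equal(o$feet, c(1L, 1L, 1L))
  expect_equal(o$legs, list(1L, 2L, 3L))
  expect_error(make_open(sir, list(5L)), "out of range")
  closed <- make_open(sir, list())
  expect_length(closed$feet, 0)
})

test_that("the vaccination composite has five species and seven transitions", {
  sv <- fixture("sviivr_components")
  comp <- oapply(sv$uwd, sv$components)
  expect_equal(nrow(comp$net$species), 5)
  expect_equal(nrow(comp$net$transitions), 7)
  # merged places take the junction labels, in junction order
  expect_equal(comp$net$species$label, c("S", "I", "R", "V", "Iv"))
  expect_length(validate_petri(comp$net), 0)
  oracle <- oracle_glue_counts(sv$uwd, sv$components)
  expect_equal(nrow(comp$net$species), oracle$species)
  expect_equal(nrow(comp$net$transitions), oracle$transitions)
})

test_that("identity wiring reproduces the component", {
  sir <- fixture("sir")
  o <- make_open(sir, list(1L, 2L, 3L))
  d <- uwd(boxes = "only", junctions = c("a", "b", "c"),
           ports = data.frame(box = rep(1, 3), junction = 1:3),
           outer_ports = data.frame(junction = 1:3))
  comp <- oapply(d, list(o))
  expect_true(petri_isomorphic(comp$net, sir))
  expect_equal(vapply(comp$legs, function(l) l[1], integer(1)), 1:3)
})

test_that("gluing two SIR copies along all three places merges species only", {
  sir <- fixture("sir")
  o <- make_open(sir, list(1L, 2L, 3L))
  d <- uwd(boxes = c("one", "two"), junctions = c("S", "I", "R"),
           ports = data.frame(box = rep(1:2, each = 3), junction = rep(1:3, 2)))
  comp <- oapply(d, list(o, o))
  expect_equal(nrow(comp$net$species), 3)
  expect_equal(nrow(comp$net$transitions), 4)
  # duplicated transition labels are qualified, not merged
  expect_false(anyDuplicated(comp$net$transitions$label) > 0)
})

test_that("species counts match the equivalence-closure oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_open_instance(seed)
    comp <- oapply(inst$uwd, inst$components)
    oracle <- oracle_glue_counts(inst$uwd, inst$components)
    expect_equal(nrow(comp$net$species), oracle$species,
                 label = paste("species count, seed", seed))
    expect_equal(nrow(comp$net$transitions), oracle$transitions,
                 label = paste("transition count, seed", seed))
    expect_length(validate_petri(comp$net), 0)
  }
})

permute_boxes <- function(d, perm) {
  inv <- order(perm)
  uwd(boxes = d$boxes$label[perm],
      ports = data.frame(box = inv[d$ports$box], junction = d$ports$junction),
      junctions = d$junctions$label,
      outer_ports = d$outer_ports)
}

test_that("box permutation yields an isomorphic composite", {
  sv <- fixture("sviivr_components")
  comp <- oapply(sv$uwd, sv$components)
  for (perm in list(c(2L, 1L, 3L), c(3L, 1L, 2L), c(3L, 2L, 1L))) {
    comp_p <- oapply(permute_boxes(sv$uwd, perm), sv$components[perm])
    expect_true(petri_isomorphic(comp$net, comp_p$net))
  }
})

test_that("composition via a flattened diagram equals composing the substituted result", {
  h <- fixture("uwd_host_vector_hier")
  host <- make_open(petri_net(c("SH", "IH"), "host_recovery",
                              data.frame(species = 2, transition = 1),
                              data.frame(species = 1, transition = 1)),
                    list(1L, 2L))
  bloodmeal <- make_open(petri_net(
    c("SH", "IH", "SV", "EV", "IV"),
    c("host_infection", "vector_exposure"),
    data.frame(species = c(1, 5, 3, 2), transition = c(1, 1, 2, 2)),
    data.frame(species = c(2, 5, 4, 2), transition = c(1, 1, 2, 2))),
    list(1L, 3L, 4L, 2L, 5L))
  aquatic <- make_open(petri_net("SV", "emergence", NULL,
                                 data.frame(species = 1, transition = 1)),
                       list(1L))
  adult <- make_open(petri_net(c("SV", "EV", "IV"), "incubation",
                               data.frame(species = 2, transition = 1),
                               data.frame(species = 3, transition = 1)),
                     list(1L, 2L, 3L))
  flat <- uwd_substitute(h$outer, h$box, h$inner)
  whole <- oapply(flat, list(host, bloodmeal, aquatic, adult))
  vector_box <- oapply(h$inner, list(aquatic, adult))
  staged <- oapply(h$outer, list(host, vector_box, bloodmeal))
  expect_true(petri_isomorphic(whole$net, staged$net))
})

test_that("oapply rejects malformed inputs", {
  sv <- fixture("sviivr_components")
  expect_error(oapply(sv$uwd, sv$components[1:2]), "one per box")
  bad <- sv$components
  bad[[1]] <- make_open(fixture("sir"), list(c(1L, 2L), 2L, 3L))
  expect_error(oapply(sv$uwd, bad), "non-singleton")
  bad2 <- sv$components
  bad2[[1]] <- make_open(fixture("sir"), list(1L, 2L))
  expect_error(oapply(sv$uwd, bad2), "ports")
})
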