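test_that("typings validate and arity-breaking typings are rejected", {
  st <- fixture("sir_typed")
  expect_true(check_typing(st)$ok)

  # an interaction-typed transition with one input arc is impossible:
  # derive_typing refuses to type unary recovery as an interaction
  expect_error(
    derive_typing(fixture("sir"), fixture("p_infectious"),
                  species_types = rep("pop", 3),
                  transition_types = c("interact", "interact")),
    "arity")

  # and a hand-built morphism doing the same fails check_typing
  pinf <- fixture("p_infectious")
  sir <- fixture("sir")
  bad <- typed_petri(sir, pinf,
                     petri_morphism(rep(1L, 3), c(3L, 3L),
                                    c(3L, 4L, 3L), c(3L, 4L, 3L)),
                     check = FALSE)
  res <- check_typing(bad)
  expect_false(res$ok)
})

test_that("the forbidden host/vector net admits no typing", {
  forb <- fixture("host_vector_sis_forbidden")
  pvb <- fixture("p_vector_borne")
  fix <- match(attr(forb, "intended_species_types"), pvb$species$label)
  expect_length(find_morphisms(forb, pvb, fix_species = fix), 0)
  # the net without the two forbidden transitions types fine
  expect_true(check_typing(fixture("host_vector_sis"))$ok)
})

test_that("typed composition succeeds on same-typed junctions and refuses clashes", {
  pvb <- fixture("p_vector_borne")
  hv <- fixture("host_vector_sis")
  open_host <- list(open = make_open(hv$net, list(1L)), typing = hv$typing)
  open_vec <- list(open = make_open(hv$net, list(3L)), typing = hv$typing)
  d <- uwd(boxes = c("a", "b"), junctions = "shared",
           ports = data.frame(box = 1:2, junction = c(1, 1)))

  glued <- typed_oapply(d, list(open_host, open_host), pvb)
  expect_true(check_typing(glued)$ok)
  # forgetful consistency: underlying net equals the untyped composite
  plain <- oapply(d, list(open_host$open, open_host$open))
  expect_identical(glued$net, plain$net)

  expect_error(typed_oapply(d, list(open_host, open_vec), pvb),
               "type clash at junction 'shared'")
})

test_that("SIR x quarantine pullback matches the pair-enumeration oracle", {
  st <- fixture("sir_typed")
  q <- fixture("quarantine")
  sq <- stratify(st, q)
  expect_equal(nrow(sq$net$species), 6)
  expect_equal(nrow(sq$net$transitions), 9)
  sizes <- oracle_pullback_sizes(st, q)
  expect_equal(nrow(sq$net$species), unname(sizes["species"]))
  expect_equal(nrow(sq$net$transitions), unname(sizes["transitions"]))
  expect_equal(nrow(sq$net$input_arcs), unname(sizes["input_arcs"]))
  expect_equal(nrow(sq$net$output_arcs), unname(sizes["output_arcs"]))
  expect_true(check_typing(sq)$ok)
  # infection survives only between non-quarantining pairs
  expect_true("infection_contact_nQ" %in% sq$net$transitions$label)
})

test_that("SIS x two-patch flux pullback has 4 places and 8 transitions", {
  sf <- stratify(fixture("sis_typed"), fixture("flux", n = 2))
  expect_equal(nrow(sf$net$species), 4)
  expect_equal(nrow(sf$net$transitions), 8)
})

test_that("both projections are valid morphisms on every fixture pairing", {
  pairs <- list(
    list(fixture("sir_typed"), fixture("quarantine")),
    list(fixture("sir_typed"), fixture("age")),
    list(fixture("sis_typed"), fixture("flux", n = 2)),
    list(fixture("sis_typed"), fixture("simple_trip", n = 2)))
  for (pr in pairs) {
    s <- stratify(pr[[1]], pr[[2]])
    expect_true(check_morphism(attr(s, "proj_disease"), s$net, pr[[1]]$net)$ok)
    expect_true(check_morphism(attr(s, "proj_strata"), s$net, pr[[2]]$net)$ok)
    # size bound: never more places than the product
    expect_lte(nrow(s$net$species),
               nrow(pr[[1]]$net$species) * nrow(pr[[2]]$net$species))
    # one-place type system: the bound is attained
    expect_equal(nrow(s$net$species),
                 nrow(pr[[1]]$net$species) * nrow(pr[[2]]$net$species))
  }
})

test_that("stratification is commutative and associative up to isomorphism", {
  st <- fixture("sir_typed")
  q <- fixture("quarantine")
  fl <- fixture("flux", n = 2)
  expect_true(petri_isomorphic(stratify(st, q)$net, stratify(q, st)$net))
  a1 <- stratify(stratify(st, q), fl)
  a2 <- stratify(st, stratify(q, fl))
  expect_equal(nrow(a1$net$species), 12)
  expect_equal(nrow(a1$net$transitions), 18)
  expect_true(petri_isomorphic(a1$net, a2$net))
})

test_that("stratifying by the identity-typed type system is a no-op", {
  pinf <- fixture("p_infectious")
  pid <- derive_typing(pinf, pinf, "pop", c("disease", "strata", "interact"))
  st <- fixture("sir_typed")
  expect_true(petri_isomorphic(stratify(st, pid)$net, st$net))
})

test_that("the pullback satisfies its universal property on a small instance", {
  st <- fixture("sir_typed")
  q <- fixture("quarantine")
  P <- stratify(st, q)
  p1 <- attr(P, "proj_disease"); p2 <- attr(P, "proj_strata")
  # a two-place net with one disease-status transition, typed likewise
  Z <- derive_typing(
    petri_net(c("z1", "z2"), "heal", data.frame(species = 1, transition = 1),
              data.frame(species = 2, transition = 1)),
    fixture("p_infectious"), c("pop", "pop"), "disease")
  fs <- find_morphisms(Z$net, st$net)
  gs <- find_morphisms(Z$net, q$net)
  over_type <- function(m, target)
    identical(morphism_key(compose_morphism(target$typing, m)),
              morphism_key(Z$typing))
  fs <- Filter(function(m) over_type(m, st), fs)
  gs <- Filter(function(m) over_type(m, q), gs)
  expect_gt(length(fs), 0); expect_gt(length(gs), 0)
  hs <- find_morphisms(Z$net, P$net)
  for (f in fs) for (g in gs) {
    matching <- Filter(function(h)
      identical(morphism_key(compose_morphism(p1, h)), morphism_key(f)) &&
      identical(morphism_key(compose_morphism(p2, h)), morphism_key(g)), hs)
    expect_length(matching, 1)  # existence and uniqueness
  }
})

test_that("infectious-typed nets balance inputs and outputs per transition", {
  for (nm in c("sir_typed", "sis_typed", "quarantine", "age")) {
    net <- fixture(nm)$net
    for (t in seq_len(nrow(net$transitions))) {
      st <- transition_stoichiometry(net, t)
      expect_equal(sum(st$inputs), sum(st$outputs))
    }
  }
})

test_that("mismatched type systems are refused", {
  expect_error(stratify(fixture("sir_typed"), fixture("host_vector_sis")),
               "identical type net")
})
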