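# Scaffold catalogue: 22 amino-acid and 14 vitamin/cofactor biosynthesis
# pathways with SYNTHETIC placeholder gene-family ids (arCOG9xxxx).
# The real pathway-to-family mapping is curation the user supplies; this
# scaffold fixes only the catalogue shape (pathway count, categories,
# plausible pathway sizes) so capacity counts live on the 0-36 scale.
pathways:
  - id: alanine
    category: amino-acid
    compound: alanine
    genes: [arCOG90001]
  - id: glycine
    category: amino-acid
    compound: glycine
    genes: [arCOG90002, arCOG90003]
  - id: serine
    category: amino-acid
    compound: serine
    genes: [arCOG90004, arCOG90005, arCOG90006]
  - id: cysteine
    category: amino-acid
    compound: cysteine
    genes: [arCOG90007, arCOG90008, arCOG90009]
  - id: aspartate
    category: amino-acid
    compound: aspartate
    genes: [arCOG90010]
  - id: asparagine
    category: amino-acid
    compound: asparagine
    genes: [arCOG90011, arCOG90012]
  - id: threonine
    category: amino-acid
    compound: threonine
    genes: [arCOG90013, arCOG90014, arCOG90015, arCOG90016]
  - id: methionine
    category: amino-acid
    compound: methionine
    genes: [arCOG90017, arCOG90018, arCOG90019, arCOG90020, arCOG90021, arCOG90022, arCOG90023]
  - id: lysine
    category: amino-acid
    compound: lysine
    genes: [arCOG90024, arCOG90025, arCOG90026, arCOG90027, arCOG90028, arCOG90029, arCOG90030, arCOG90031, arCOG90032]
  - id: isoleucine
    category: amino-acid
    compound: isoleucine
    genes: [arCOG90033, arCOG90034, arCOG90035, arCOG90036, arCOG90037, arCOG90038, arCOG90039, arCOG90040]
  - id: leucine
    category: amino-acid
    compound: leucine
    genes: [arCOG90041, arCOG90042, arCOG90043, arCOG90044, arCOG90045, arCOG90046, arCOG90047, arCOG90048]
  - id: valine
    category: amino-acid
    compound: valine
    genes: [arCOG90049, arCOG90050, arCOG90051, arCOG90052, arCOG90053, arCOG90054, arCOG90055]
  - id: glutamate
    category: amino-acid
    compound: glutamate
    genes: [arCOG90056]
  - id: glutamine
    category: amino-acid
    compound: glutamine
    genes: [arCOG90057]
  - id: proline
    category: amino-acid
    compound: proline
    genes: [arCOG90058, arCOG90059, arCOG90060, arCOG90061]
  - id: arginine
    category: amino-acid
    compound: arginine
    genes: [arCOG90062, arCOG90063, arCOG90064, arCOG90065, arCOG90066, arCOG90067, arCOG90068, arCOG90069]
  - id: histidine
    category: amino-acid
    compound: histidine
    genes: [arCOG90070, arCOG90071, arCOG90072, arCOG90073, arCOG90074, arCOG90075, arCOG90076, arCOG90077]
  - id: phenylalanine
    category: amino-acid
    compound: phenylalanine
    genes: [arCOG90078, arCOG90079, arCOG90080, arCOG90081, arCOG90082, arCOG90083, arCOG90084, arCOG90085, arCOG90086]
  - id: tyrosine
    category: amino-acid
    compound: tyrosine
    genes: [arCOG90087, arCOG90088, arCOG90089, arCOG90090, arCOG90091, arCOG90092, arCOG90093, arCOG90094, arCOG90095]
  - id: tryptophan
    category: amino-acid
    compound: tryptophan
    genes: [arCOG90096, arCOG90097, arCOG90098, arCOG90099, arCOG90100, arCOG90101, arCOG90102, arCOG90103, arCOG90104, arCOG90105]
  - id: selenocysteine
    category: amino-acid
    compound: selenocysteine
    genes: [arCOG90106, arCOG90107, arCOG90108]
  - id: pyrrolysine
    category: amino-acid
    compound: pyrrolysine
    genes: [arCOG90109, arCOG90110, arCOG90111, arCOG90112]
  - id: cofactor_f430
    category: vitamin-cofactor
    compound: cofactor F430
    genes: [arCOG90113, arCOG90114, arCOG90115, arCOG90116, arCOG90117]
  - id: coenzyme_f420
    category: vitamin-cofactor
    compound: coenzyme F420
    genes: [arCOG90118, arCOG90119, arCOG90120, arCOG90121, arCOG90122, arCOG90123]
  - id: methanofuran
    category: vitamin-cofactor
    compound: methanofuran
    genes: [arCOG90124, arCOG90125, arCOG90126, arCOG90127, arCOG90128, arCOG90129, arCOG90130]
  - id: methanopterin
    category: vitamin-cofactor
    compound: methanopterin
    genes: [arCOG90131, arCOG90132, arCOG90133, arCOG90134, arCOG90135, arCOG90136, arCOG90137, arCOG90138, arCOG90139]
  - id: coenzyme_m
    category: vitamin-cofactor
    compound: coenzyme M
    genes: [arCOG90140, arCOG90141, arCOG90142, arCOG90143, arCOG90144]
  - id: coenzyme_b
    category: vitamin-cofactor
    compound: coenzyme B
    genes: [arCOG90145, arCOG90146, arCOG90147, arCOG90148, arCOG90149, arCOG90150]
  - id: cobalamin
    category: vitamin-cofactor
    compound: cobalamin
    genes: [arCOG90151, arCOG90152, arCOG90153, arCOG90154, arCOG90155, arCOG90156, arCOG90157, arCOG90158, arCOG90159, arCOG90160, arCOG90161, arCOG90162, arCOG90163, arCOG90164, arCOG90165, arCOG90166, arCOG90167, arCOG90168, arCOG90169, arCOG90170]
  - id: biotin
    category: vitamin-cofactor
    compound: biotin
    genes: [arCOG90171, arCOG90172, arCOG90173, arCOG90174, arCOG90175, arCOG90176]
  - id: thiamine
    category: vitamin-cofactor
    compound: thiamine
    genes: [arCOG90177, arCOG90178, arCOG90179, arCOG90180, arCOG90181, arCOG90182, arCOG90183, arCOG90184]
  - id: riboflavin
    category: vitamin-cofactor
    compound: riboflavin
    genes: [arCOG90185, arCOG90186, arCOG90187, arCOG90188, arCOG90189, arCOG90190]
  - id: nad
    category: vitamin-cofactor
    compound: NAD
    genes: [arCOG90191, arCOG90192, arCOG90193, arCOG90194, arCOG90195, arCOG90196, arCOG90197]
  - id: folate
    category: vitamin-cofactor
    compound: folate
    genes: [arCOG90198, arCOG90199, arCOG90200, arCOG90201, arCOG90202, arCOG90203, arCOG90204, arCOG90205]
  - id: coenzyme_a
    category: vitamin-cofactor
    compound: coenzyme A
    genes: [arCOG90206, arCOG90207, arCOG90208, arCOG90209, arCOG90210, arCOG90211, arCOG90212, arCOG90213]
  - id: molybdopterin
    category: vitamin-cofactor
    compound: molybdopterin
    genes: [arCOG90214, arCOG90215, arCOG90216, arCOG90217, arCOG90218, arCOG90219]
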