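# Default parameterization of the NAD salvage network.
#
# Units: kcat 1/s (at base_temperature_K), Km mM, Ea kJ/mol, enzymes nM,
# metabolites mM. Michaelis-Menten rate laws are irreversible and first
# order in the pyridine substrate only; ATP/PRPP/phosphate cosubstrates
# are held constant and absorbed into kcat. The shared activation energy
# of 65 kJ/mol puts every enzymatic Q10 at ~2.2 (310.65 K), inside the
# physiological 2-3 band. kcat and Km values are plausible defaults in
# the ranges reported for these enzyme families, not measurements.
base_temperature_K: 310.65
pyridine_total_mM: 0.3
reactions:
  NCE:
    enzyme: NCE
    substrate: NAD
    product: Nam
    kcat: 10
    Km: 0.2
    Ea: 65
    atp_cost: 0
  PncA:
    enzyme: PncA
    substrate: Nam
    product: NA
    kcat: 10
    Km: 0.1
    Ea: 65
    atp_cost: 0
  Nampt:
    enzyme: Nampt
    substrate: Nam
    product: NMN
    kcat: 5
    Km: 0.005
    Ea: 65
    atp_cost: 1
  PncB:
    enzyme: PncB
    substrate: NA
    product: NAMN
    kcat: 10
    Km: 0.02
    Ea: 65
    atp_cost: 1
  NadD_NMN:
    enzyme: NadD
    substrate: NMN
    product: NAD
    kcat: 20
    Km: 0.1
    Ea: 65
    atp_cost: 1
  NadD_NAMN:
    enzyme: NadD
    substrate: NAMN
    product: NAAD
    kcat: 20
    Km: 0.05
    Ea: 65
    atp_cost: 1
  NadE:
    enzyme: NadE
    substrate: NAAD
    product: NAD
    kcat: 20
    Km: 0.1
    Ea: 65
    atp_cost: 2
  NadR_NR:
    enzyme: NadR
    substrate: NR
    product: NMN
    kcat: 10
    Km: 0.1
    Ea: 65
    atp_cost: 1
  NadR_NAR:
    enzyme: NadR
    substrate: NAR
    product: NAMN
    kcat: 10
    Km: 0.1
    Ea: 65
    atp_cost: 1
  SurE_NMN:
    enzyme: SurE
    substrate: NMN
    product: NR
    kcat: 5
    Km: 0.5
    Ea: 65
    atp_cost: 0
  SurE_NAMN:
    enzyme: SurE
    substrate: NAMN
    product: NAR
    kcat: 5
    Km: 0.5
    Ea: 65
    atp_cost: 0
  PNP_NR:
    enzyme: PNP
    substrate: NR
    product: Nam
    kcat: 20
    Km: 0.3
    Ea: 65
    atp_cost: 0
  PNP_NAR:
    enzyme: PNP
    substrate: NAR
    product: NA
    kcat: 20
    Km: 0.3
    Ea: 65
    atp_cost: 0
# Non-enzymatic glycohydrolysis. "fitted" derives k(T0) and Ea per
# compound by refitting the bundled thermolysis rate table; an explicit
# block (k_per_s_at_T0, Ea) overrides it.
hydrolysis:
  source: fitted
  reactions:
    hyd_NAD: {substrate: NAD, product: Nam}
    hyd_NMN: {substrate: NMN, product: Nam}
    hyd_NR: {substrate: NR, product: Nam}
    hyd_NAR: {substrate: NAR, product: NA}
    hyd_NAMN: {substrate: NAMN, product: NA}
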