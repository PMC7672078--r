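# mend_defaults v1 -- fixed (non-calibrated) parameters of the
# microbial-enzyme decomposition model with dormancy.
# Units: rates h^-1 unless noted; concentrations mg C cm^-3 soil;
# activation energies kJ mol^-1; temperatures degC.
# Every value can be overridden via fixed_params(...).

[decomposition]
VP1  = 2.5      # max specific decomposition of oxidative POC, mg C mg^-1 enzyme C h^-1
VP2  = 2.5      # max specific decomposition of hydrolytic POC
VM   = 1.0      # max specific decomposition of mineral-associated OC
KP1  = 50       # half-saturation for P1 decomposition
KP2  = 50       # half-saturation for P2 decomposition
KM   = 250      # half-saturation for M decomposition

[sorption]
Kads = 0.006    # DOC adsorption rate constant
Kdes = 0.001    # DOC desorption rate constant
Qmax = 1.7      # adsorption capacity of the mineral phase

[partition]
fD   = 0.5      # fraction of decomposed POC routed to DOC (rest to MOC)
gD   = 0.5      # fraction of dead biomass routed to DOC (rest to P2)

[microbial_turnover]
rM   = 0.0018   # specific mortality rate of active biomass
beta = 1e-4     # dormant maintenance relative to active maintenance

[enzymes]
pEP1 = 2e-5     # specific production rate of P1-degrading enzymes
pEP2 = 2e-5     # specific production rate of P2-degrading enzymes
pEM  = 5e-5     # specific production rate of M-degrading enzymes
rE   = 1e-3     # enzyme turnover rate (returns to DOC)

[temperature]
Ea_V   = 47     # activation energy of V-type maximum rates
Ea_K   = 19     # activation energy of half-saturation constants
Ea_ads = 10     # activation energy of sorption rate constants
kYg    = -0.01  # temperature slope of carbon use efficiency, degC^-1
Tref   = 20     # reference temperature
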