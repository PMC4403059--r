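# Synthetic Gaussian band parameters for the simulated three-compound
# system (dilute-acid UV region, 200-300 nm). These are NOT measured
# absorptivities: they qualitatively mimic the band positions, relative
# intensities and overlap of a ternary analgesic/antihistamine/decongestant
# formulation so that the zero-crossing workflow can be exercised end to
# end. epsilon_peak is in AU mL ug^-1 cm^-1.
compound_id,center_nm,sigma_nm,epsilon_peak
acetaminophen,243,10.8,0.066
acetaminophen,208.1,8,0.030
diphenhydramine,221.1,7,0.40
diphenhydramine,253,4,0.0012
diphenhydramine,258,4,0.0016
pseudoephedrine,205,3.5,0.50
pseudoephedrine,251,2.8,0.0009
pseudoephedrine,257,2.8,0.0011
pseudoephedrine,263,2.8,0.0008
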