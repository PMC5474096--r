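archaeal_virus: spindle-shaped virus
archaeal_virus: fusellovirus
archaeal_virus: rudivirus
archaeal_virus: lipothrixvirus
archaeal_virus: bicaudavirus
archaeal_virus: ampullavirus
archaeal_virus: globulovirus
archaeal_virus: salterprovirus
archaeal_virus: turreted icosahedral virus
archaeal_virus: pleolipovirus
archaeal_virus: halovirus
archaeal_virus: Sulfolobus
archaeal_virus: Acidianus
archaeal_virus: Aeropyrum
archaeal_virus: Pyrococcus
archaeal_virus: Thermoproteus
archaeal_virus: Pyrobaculum
archaeal_virus: Methanobacterium phage
archaeal_virus: Methanothermobacter
archaeal_virus: Methanococcus voltae
archaeal_virus: Haloarcula
archaeal_virus: Halorubrum
archaeal_virus: Haloferax
archaeal_virus: Halogeometricum
archaeal_virus: Natrialba
archaeal_virus: His1 virus
archaeal_virus: His2 virus
archaeal_virus: psiM2
archaeal_virus: BJ1 virus
eukaryotic_virus: mimivirus
eukaryotic_virus: herpesvirus
eukaryotic_virus: phycodnavirus
eukaryotic_virus: Chlorella virus
eukaryotic_virus: Ostreococcus virus
eukaryotic_virus: Emiliania huxleyi virus
eukaryotic_virus: Micromonas virus
eukaryotic_virus: baculovirus
eukaryotic_virus: poxvirus
eukaryotic_virus: iridovirus
eukaryotic_virus: adenovirus
eukaryotic_virus: influenza
eukaryotic_virus: coccolithovirus
phage: phage
phage: Myoviridae
phage: Siphoviridae
phage: Podoviridae
phage: prophage
phage: virus
cellular: bacterium
cellular: bacteria
cellular: archaeon
cellular: archaea
cellular: eukaryota
cellular: Candidatus
cellular: uncultured organism
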