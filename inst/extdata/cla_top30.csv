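taxon_name,family,ur,ci,pfaf,fff
Thymus vulgaris L.,Lamiaceae,957,0.52,1,1
Foeniculum vulgare Mill. subsp. piperitum (Ucria) Cout.,Apiaceae,482,0.24,1,1
Laurus nobilis L.,Lauraceae,475,0.27,1,0
Rubus ulmifolius Schott,Rosaceae,425,0.25,1,0
Mentha spicata L.,Lamiaceae,415,0.23,1,1
Rosmarinus officinalis L.,Lamiaceae,356,0.21,1,1
Origanum vulgare L.,Lamiaceae,341,0.20,1,1
Ficus carica L.,Moraceae,317,0.17,1,0
Satureja montana L.,Lamiaceae,285,0.14,1,1
Reichardia picroides (L.) Roth,Asteraceae,249,0.15,1,0
Arbutus unedo L.,Ericaceae,234,0.14,1,0
Cynara cardunculus L.,Asteraceae,222,0.13,1,0
Chondrilla juncea L.,Asteraceae,220,0.13,1,0
Silene vulgaris (Moench) Garcke,Caryophyllaceae,198,0.10,1,0
Portulaca oleracea L.,Portulacaceae,191,0.12,1,0
Urtica dioica L.,Urticaceae,188,0.11,1,1
Taraxacum officinale Weber in Wiggers,Asteraceae,173,0.10,1,1
Asparagus acutifolius L.,Asparagaceae,145,0.09,1,1
Cichorium intybus L.,Asteraceae,145,0.08,1,0
Sorbus domestica L.,Rosaceae,143,0.09,1,0
Papaver rhoeas L.,Papaveraceae,140,0.09,0,1
Thymus serpyllum L.,Lamiaceae,121,0.07,0,1
Rorippa nasturtium-aquaticum (L.) Hayek,Brassicaceae,118,0.07,0,1
Molopospermum peloponnesiacum (L.) Koch,Apiaceae,111,0.07,0,0
Borago officinalis L.,Boraginaceae,109,0.05,1,1
Rubus idaeus L.,Rosaceae,109,0.07,1,1
Celtis australis L.,Cannabaceae,108,0.07,0,1
Sambucus nigra L.,Adoxaceae,103,0.06,0,1
Sonchus oleraceus L.,Asteraceae,102,0.06,0,1
Fragaria vesca L.,Rosaceae,94,0.06,0,1
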