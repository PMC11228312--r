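# Drug lexicon for the bevacizumab regimen analysis.
# Names are normalized (trimmed, case-folded) at load time; matching against
# DRUGNAME is exact on the normalized form, never substring-based.

[index]
Bevacizumab
Avastin

[biosimilar_deny]            # regex patterns; matching names never count as index drug
^bevacizumab-
^bevacizumab .*biosimilar

[chemotherapy]
# platinum drugs
Cisplatin
Carboplatin
Paraplatin
Nedaplatin
Oxaliplatin
# pemetrexed
Pemetrexed
Alimta
# gemcitabine
Gemcitabine
Gemzar
# taxoids
Paclitaxel
Taxol
Albumin-bound paclitaxel
Nab-paclitaxel
Abraxane
Docetaxel
Taxotere
Anzatax
# vinca alkaloids
Vindesine
Vinorelbine
Navelbine
# etoposide
Etoposide
VP-16
# others
Irinotecan
Topotecan
Mitomycin
Amrubicin
Ifosfamide
Cyclophosphamide
Bortezomib
Everolimus
Temozolomide
Thalomid
Capecitabine
Fluorouracil
5-FU

[ici]
# anti-PD-1
Nivolumab
Pembrolizumab
Cemiplimab
Opdivo
Keytruda
Libtayo
# anti-PD-L1
Atezolizumab
Durvalumab
Avelumab
Imfinzi
Bavencio
Tecentriq
# anti-CTLA-4
Ipilimumab
Tremelimumab
Yervoy

[targeted]
# EGFR-TKI
Iressa
Gefitinib
Tarceva
Erlotinib
Gilotrif
Afatinib
Tagrisso
Osimertinib
Dacomitinib
Vizimpro
Lapatinib
Tykerb
Icotinib
Conmana
# EGFR antibody
Cetuximab
Erbitux
# ALK-TKI
Crizotinib
Xalkori
Alectinib
Alecensa
Ceritinib
Zykadia
Entrectinib
Rozlytrek
Brigatinib
Alunbrig
Lorlatinib
Lorviqua
# others
Cediranib
Temsirolimus
CCI-779
Endostatin
Sorafenib
Herceptin
Trastuzumab
Rituxan
Rituximab
Trebananib
AMG 386
Faslodex
Lucentis
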