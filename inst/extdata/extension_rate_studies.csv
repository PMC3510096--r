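species,extension_mm_yr,location
P_lobata,14.9,"Ambon, Indonesia"
P_lobata,11.5,"Cano Island, Costa Rica"
P_lobata,14.3,"Java, Indonesia"
P_lobata,12.2,"Lahaina, Maui, Hawaii"
P_lobata,11.0,"Oahu, Hawaii"
P_lobata,6.4,"Oahu, Hawaii"
P_lobata,7.8,"Olosega, American Samoa"
P_lobata,14.7,"Sulawesi, Indonesia"
P_lutea,22.4,"Abaiang Atoll, Kiribati"
P_lutea,5.7,"Eilat, Gulf of Aqaba"
P_lutea,7.6,"Enewetak, Marshall Islands"
P_lutea,19.4,"Koh Phuket, South Thailand"
P_lutea,9.8,"Kota Bontang, Indonesia"
P_lutea,11.0,"Moorea, Society Islands"
P_lutea,16.7,"Shikoku, Japan"
A_muricata,123.3,"Davies Reef, GBR"
A_muricata,116.3,"Hikkaduwa Nature Reserve"
A_muricata,62.6,"Houtman Abrolhos, Western Australia"
A_muricata,34.2,"Magnetic Island, Australia"
A_muricata,39.6,"Magnetic Island, Australia"
A_muricata,86.4,"Phuket, Thailand"
P_damicornis,32.2,"Cano Island, Costa Rica"
P_damicornis,50.2,"Contadora Island, Panama"
P_damicornis,25.0,"Guam, Philippine Sea"
P_damicornis,16.1,"Lord Howe Island, GBR"
P_damicornis,18.5,"Oahu, Hawaii"
P_damicornis,18.6,"Oahu, Hawaii"
P_damicornis,59.1,"Pearl Islands, Panama"
P_damicornis,18.0,"Phuket, Thailand"
P_damicornis,11.0,"Rottnest Island, WA"
P_damicornis,12.4,"Solitary Islands, GBR"
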