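species,cephalic_status
Androlaelaps casalis,micro
Eviphis ostrinus,micro
Geholaspis longispinosus,micro
Glyphtholaspis confusa,micro
Pachylaelaps furcifer,micro
Pachylaelaps leauchlii,micro
Porrhostaspis lunulata,micro
Trachytes aegrota,micro
Urodiaspis tecta,micro
Uropoda orbicularis DN,micro
Alliphis siculus,mega
Geholaspis sp.,mega
Parasitus lunaris DN,mega
Pergamasus mirabilis,mega
Pergamasus quisquillarum,mega
Pergamasus runcatellus,mega
Pergamasus septentrionalis,mega
Pergamasus sp,mega
Rhodacarellus epigynalis,mega
Rhodacarus agrestis,mega
Rhodacarus strenzkei,mega
Veigaia cerva,mega
Veigaia nemorensis (new),mega
Veigaia nemorensis (old),mega
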