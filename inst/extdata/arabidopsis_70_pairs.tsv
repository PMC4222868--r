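FWgene	RVgene	len	DRE	CE3	FWannotation	RVannotation	FWlocation	RVlocation
AT1G04635	AT1G04630	202	y		AtPOP5	maternal effect embryo arrest 4 (MEE4)	nucleolus	mitochondrion
AT1G07510	AT1G07500	347			FtsH10 protease	unknown protein	mitochondrion	cytosol
AT1G07660	AT1G07645	452			Histone superfamily	vicinal oxygen chelate (VOC) metalloenzyme	nucleus	cytosol
AT1G07985	AT1G07980	478			Expressed protein	nuclear factor Y, subunit C10	nucleus	plastid
AT1G15330	AT1G15320	333			Cystathionine beta-synthase (CBS)	unknown protein	cytosol	extracellular
AT1G16740	AT1G16730	378			Ribosomal protein L20	unknown protein 6 (UP6)	mitochondrion	nucleus
AT1G19980	AT1G19970	327			cytomatrix protein-related	ER lumen protein retaining receptor family	nucleus	ER
AT1G28540	AT1G28530	164			unknown protein	unknown protein	cytosol	plastid
AT1G31420	AT1G31410	259	y		LRR kinase (FEI1)	putrescine-binding transporter protein	membrane	plastid
AT1G32560	AT1G32550	367	y		LEA4-1	Ferredoxin C2	nucleus	plastid
AT1G48840	AT1G48830	264	y		unknown function (DUF639)	Ribosomal protein S7e family	membrane	cytosol
AT1G50440	AT1G50430	161			RING/FYVE/PHD zinc finger	DWARF 5 (DWF5) -STEROL DELTA7 REDUCTASE	nucleus	membrane
AT1G52230	AT1G52220	139			PHOTOSYSTEM I SUBUNIT H2	unknown protein	plastid	plastid
AT1G54870	AT1G54860	375			ChlADR aldehyde reductase	Glycoprotein membrane GPI-anchored	cytosol	extracellular
AT1G56170	AT1G56165	391			CCAAT motif binding complex	non-coding RNA	nucleus	cytosol
AT1G61790	AT1G61780	237			Oligosaccharyltransferase	postsynaptic protein-related	ER	nucleus
AT1G65140	AT1G65130	595			Ubiquitin c-terminal hydrolase	Ubiquitin c-terminal hydrolase	cytosol	nucleus
AT1G71090	AT1G71080	370			Auxin efflux carrier	RNA pol II transcription elongation factor	membrane	nucleus
AT1G72030	AT1G72020	434			Acyl-CoA N-acyltransferase	unknown protein	plastid	mitochondrion
AT1G77370	AT1G77360	307			Glutaredoxin	Tetratricopeptide repeat (TPR)-like	extracellular	mitochondrion
AT2G20490	AT2G20480	189			NOP10; EDA27 (RNA binding)	unknown protein	nucleolus	nucleus
AT2G25890	AT2G25880	470			Oleosin	Ser/Thr kinases - Ataurora2 (AUR2)	lipid body	nucleus
AT2G29560	AT2G29550	523			phosphoenolpyruvate enolase	beta-tubulin (TUB7)	cytosol	nucleus
AT2G38040	AT2G38025	385	y		acetyl-CoA carboxylase subunit	Cysteine proteinase superfamily	plastid	plastid
AT2G38660	AT2G38650	183			Amino acid dehydrogenase	galacturonosyltransferase 7 (GAUT7)	mitochondrion	golgi
AT2G39460	AT2G39450	331	y		60S ribosomal protein L23aA	manganese transporter	cytosol	golgi
AT2G43190	AT2G43180	187			AtPOP4 (RNA processing)	Phosphoenolpyruvate carboxylase family	nucleolus	plastid
AT2G45740	AT2G45730	556	y		peroxin11 (PEX11) family	eukaryotic initiation factor 3 subunit	peroxisome	cytosol
AT3G03160	AT3G03150	264	y	y	unknown protein	unknown protein	endomembrane	mitochondrion
AT3G03320	AT3G03310	135			RNA-binding protein	lecithin:cholesterol acyltransferase 3	cytosol	plasma membrane
AT3G12320	AT3G12300	580	y		unknown protein	unknown protein	nucleus	cytosol
AT3G13190	AT3G13180	559			unknown function (DUF827)	rRNA small subunit methyltransferase B	nucleus	plastid
AT3G14340	AT3G14330	305			unknown protein	Tetratricopeptide repeat (TPR)-like	membrane	mitochondrion
AT3G15290	AT3G15280	304			3-hydroxyacyl-CoA DH	unknown protein	peroxisome	mitochondrion
AT3G16010	AT3G16000	197			PPR-like superfamily	plastid DNA-binding protein; MFP1	mitochondrion	plastid
AT3G18215	AT3G18210	245			unknown function, DUF599	2OG and Fe(II)-dependent oxygenase	membrane	nucleus
AT3G26618	AT3G26616	464			eukaryotic release factor 1-3	unknown protein	cytosol	cytosol
AT3G52230	AT3G52220	139			unknown protein	Kinase phosphorylation domain	plastid	nucleus
AT3G53180	AT3G53170	477			glutamate-ammonia ligases	Tetratricopeptide repeat (TPR)-like	cytosol	cytosol
AT3G59500	AT3G59490	190			HRF1 family protein	unknown protein	ER membrane	nucleus
AT4G00030	AT4G00026	168			Plastid-lipid associated (PAP)	SD3 (Segregation Distortion 3); TIM21	plastid	mitochondrion
AT4G01270	AT4G01265	577	y		RING/U-box superfamily	raffinose synthase family pseudogene	nucleus	NA
AT4G02430	AT4G02425	189	y		S/R-Rich Protein Splicing Factors	unknown protein	nucleus	nucleus
AT4G11985	AT4G11980	129			pre-tRNA/non-coding RNA	nudix hydrolase homolog 14	nucleus/cytosol	plastid
AT4G16160	AT4G16155	205	y		OEP16-S	dihydrolipoyl dehydrogenase	plastid	plastid
AT4G17560	AT4G17550	541	y		Ribosomal protein L19 family	glycerol-3-phosphate permease gene family	plastid	mitochondrion
AT4G17730	AT4G17720	440			syntaxin23	RNA-binding (RRM/RBD/RNP motifs) family	cytosol	cytosol
AT4G18240	AT4G18230	169			starch synthase 4 (SS4)	unknown protein	plastid	plasma membrane
AT4G18370	AT4G18360	447			DEG5 - photosystem II repair	Aldolase-type TIM barrel family	plastid	peroxisome
AT4G19020	AT4G19010	277			chromomethylase 2 (CMT2)	AMP-dependent synthetase and ligase family	nucleus	peroxisome
AT4G21280	AT4G21270	267			PsbQ subunit photosystem II	kinesin-like motor protein	plastid	nucleus
AT4G23840	AT4G23820	254			Leucine-rich repeat (LRR) family	Pectin lyase-like superfamily	cytosol	extracellular
AT4G25140	AT4G25130	366			Oleosin1	chloroplast methionine sulfoxide reductase	lipid body	plastid
AT4G25580	AT4G25570	561			cold acclimation protein (CAP160)	cytochrome b561	nucleus	plasma membrane
AT4G31080	AT4G31070	351			unknown function (DUF2296)	Tetratricopeptide repeat (TPR)-like	ER	cytosol
AT4G33540	AT4G33530	365			metallo-beta-lactamase family	K + UPTAKE PERMEASE 5 (KUP5)	plastid	plasma membrane
AT5G05490	AT5G05480	293			SYN1 (RAD21-like) gene	Peptide-N4-asparagine amidase A protein	nucleus	plasma membrane
AT5G05987	AT5G05980	509	y		prenylated RAB acceptor 1.A2	folylpolyglutamate synthetase isoform	membrane	mitochondrion
AT5G07320	AT5G07315	363			Mito ATP-Mg/Pi transporter	pre-tRNA/non-coding RNA	mitochondrion	nucleus/cytosol
AT5G10080	AT5G10070	409			Eukaryotic aspartyl protease	RNase L inhibitor protein-related	membrane	cytosol
AT5G10745	AT5G10740	275			unknown protein	Protein phosphatase 2C family protein	membrane	nucleus
AT5G16760	AT5G16750	331			inositol-trisphosphate 5/6-kinase	TORMOZEMBRYO DEFECTIVE (TOZ)	cytosol	nucleolus
AT5G37350	AT5G37340	232			RIO1 kinase	ZPR1 zinc-finger domain protein	nucleus	cytosol
AT5G51540	AT5G51530	529			Zincin-like metalloproteases	Ubiquitin c-terminal hydrolase	plastid	cytosol
AT5G54062	AT5G54060	424			unknown protein	anthocyanin 3-O-glucoside	extracellular	membrane
AT5G54970	AT5G54960	449			unknown protein	pyruvate decarboxylase-2	cytosol	cytosol
AT5G61940	AT5G61930	481	y		Ubiquitin c-terminal hydrolase	ACCUMULATION OF PHOTOSYSTEM ONE 3	nucleus	mitochondrion
AT5G62490	AT5G62480	537			AtHVA22 family	glutathione transferase	extracellular	cytosol
AT5G64220	AT5G64210	582			Calmodulin-binding activator	isoform of alternative oxidase	nucleus	mitochondrion
AT5G67230	AT5G67220	514			GT43 glycosyltransferase family	FMN-linked oxidoreductase superfamily	mitochondrion	mitochondrion
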