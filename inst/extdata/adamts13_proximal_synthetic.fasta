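>ADAMTS13_proximal_synthetic offset=75 (synthetic scaffold; see package docs)
AAGGILHLELLVAVGPDVFQAHQEDTERYVLTNLNIGAELLRDPSLGAQFRVHLVKMVIL
TEPEGDFLPGSEWTLRFNTRTTMEQTINPEDDTDPGHADLVLYITRFDLELPDGNRQVRG
DDFECAWWTNLHRCTQVWFVQPSAIKAASRWRGIQMKYTWDGAPGSGCGPSGHVMASDGA
APRAGLAWSPCSRRQLLSLLSAGRARCVWDPPRPQPGSAGHPPDAQPGLYYSANEQCRVA
FGPKAVACTFAREHLDMCQALSCHTDPLDQSSCSRHFKQKEDFFDAGTIYWCSKGRCRSL
VELTPIAAVHLAQIYIHDPPFGPCVKDCCRWYCKPDHDYRIYDSQFMPYNTDGFFINITM
MQRQKKTQLEFMSQQCARTDGQPLRSSPGGASFYHWGAAVPHSQGSWLPVHAEITNTVRE
ETNKRDSFLDGTRCMPSGPREDGTLSLCVSGSCRTFGCDGRWRHDFILNRGESPCRDKKL
CSPRKGSFTAGRAREYVTFLTVTPNLTSVYIANHRPLFTHLAVRIGGRYVVAGKMSISPN
TTYPSLLEDGRVEYRVALTEDRLPRLEEIRIWGPLQEDADIQVYRRYGEEYGNLTRPDIT
FTYFQPKPRQ
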